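#' Re-exported generics and their methods
#'
#' `tidy()`/`glance()` methods summarise fitted objects
#' ([train_size_ff_model()], [build_reference()]); `autoplot()` methods
#' draw the standard figure for a result table.
#'
#' @name generics_reexports
#' @param x,... object and further arguments passed to methods.
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
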