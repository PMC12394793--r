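#' AcylMS: direct MS/MS analysis of S-acylated and prenylated peptides
#'
#' Fragment-ion modeling with lipid-specific neutral-loss channels,
#' spectrum annotation and site localization, in-silico digestion, a
#' miniature target-decoy database search, and MS1 stability
#' quantification, plus simulators that generate ground-truth fixtures.
#'
#' @name AcylMS-package
#' @aliases AcylMS
#' @import methods
#' @importFrom utils read.delim write.table head tail
#' @importFrom stats runif rnorm rlnorm dnorm t.test aov TukeyHSD setNames
"_PACKAGE"
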