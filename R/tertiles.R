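# Shared tertile classifier used for dwelling price classes, household
# income strata and income-class discretization. Boundary values go to the
# lower class; a degenerate middle (all values equal, or tied tertile cuts)
# collapses the tied values to the intermediate class.

tertile_cuts <- function(x) {
  stats::quantile(x, c(1 / 3, 2 / 3), names = FALSE, type = 7)
}

classify_by_cuts <- function(x, q, labels = INCOME_CLASSES) {
  cls <- ifelse(x <= q[1], 1L, ifelse(x <= q[2], 2L, 3L))
  if (q[1] == q[2]) cls[x == q[1]] <- 2L
  labels[cls]
}

tertile_classes <- function(x, labels = INCOME_CLASSES) {
  if (length(x) == 0L) return(character(0))
  classify_by_cuts(x, tertile_cuts(x), labels)
}
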