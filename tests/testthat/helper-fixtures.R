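# Small in-code fixtures.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

# A labeled toy experiment: nU users per class, nD days each; class-B days
# shifted upward by `shift` SDs on a handful of features. shift = 0 gives
# pure noise (chance-level separability).
toyObservations <- function(nU = 10, nD = 5, shift = 3, seed = 1,
                            classes = c("none", "severe")) {
  set.seed(seed)
  n <- 2 * nU * nD
  feats <- digiphen::featureLayout()
  m <- matrix(abs(rnorm(length(feats) * n, 10, 2)), nrow = length(feats),
              dimnames = list(feats, NULL))
  lab <- rep(classes, each = nU * nD)
  m[1:6, lab == classes[2]] <- m[1:6, lab == classes[2]] + shift * 2
  uid <- rep(sprintf("u%03d", 1:(2 * nU)), each = nD)
  cd <- S4Vectors::DataFrame(
    user_id = uid,
    local_date = rep(as.Date("2021-11-02") + seq_len(nD) - 1, 2 * nU),
    complete = TRUE,
    label = factor(lab, levels = classes))
  colnames(m) <- sprintf("%s.%d", uid, rep(seq_len(nD), 2 * nU))
  rownames(cd) <- colnames(m)
  new("DigitalPhenotypeExperiment",
      SummarizedExperiment(assays = list(features = m), colData = cd),
      kSd = 1)
}
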