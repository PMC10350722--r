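# Independent oracles, kept deliberately naive so they cannot share a bug
# with the implementation they check.

# literal enumeration of the nine QIDS criterion values
oracle_qids_sum <- function(s) {
  stopifnot(length(s) == 16L)
  names(s) <- paste0("QIDS", 1:16)
  max(s["QIDS1"], s["QIDS2"], s["QIDS3"], s["QIDS4"]) +
    max(s["QIDS6"], s["QIDS7"], s["QIDS8"], s["QIDS9"]) +
    max(s["QIDS15"], s["QIDS16"]) +
    s["QIDS5"] + s["QIDS10"] + s["QIDS11"] + s["QIDS12"] + s["QIDS13"] +
    s["QIDS14"]
}

# two-pass textbook Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_sd <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))

# difference-in-differences: OLS of per-patient change on arm; with
# complete balanced two-timepoint data this equals the random-intercept
# mixed-model interaction estimate
oracle_did <- function(scores, arms, t0, t1) {
  w <- merge(scores[scores$timepoint == t0, c("patient_id", "value")],
             scores[scores$timepoint == t1, c("patient_id", "value")],
             by = "patient_id")
  w$change <- w$value.y - w$value.x
  w$pt <- as.integer(arms[w$patient_id] == "PT")
  unname(coef(lm(change ~ pt, data = w))["pt"])
}
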