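# Build a response cube from wide score matrices (one per timepoint,
# patients x item_ids); NA cells are simply absent responses.
cube_from_scores <- function(by_tp, arms, scales = builtin_scales(),
                             expectancy = NULL) {
  rows <- do.call(rbind, lapply(names(by_tp), function(tp) {
    m <- by_tp[[tp]]
    data.frame(patient_id = rep(rownames(m), ncol(m)),
               timepoint = tp,
               item_id = rep(colnames(m), each = nrow(m)),
               score = as.vector(m))
  }))
  rows <- rows[!is.na(rows$score), ]
  pids <- rownames(by_tp[[1L]])
  response_cube(rows,
                arms = data.frame(patient_id = pids, arm = arms),
                expectancy = expectancy, scales = scales)
}

# a QIDS-only cube: 16 columns in QIDS order
qids_cube <- function(by_tp, arms) {
  by_tp <- lapply(by_tp, function(m) {
    colnames(m) <- paste0("QIDS", 1:16)
    m
  })
  cube_from_scores(by_tp, arms)
}

# small custom instrument for container-level tests
toy_scales <- function(n_items = 4L, n_options = 4L) {
  items <- lapply(seq_len(n_items), function(i)
    item_definition(paste0("T", i), paste("toy item", i), n_options))
  list(TOY = scale_definition("TOY", items))
}

# a 59-patient QIDS cohort with planted highest-item switching:
# switchers score one item highest at baseline and a different one at week 6
planted_cohort <- function(n_sleep = 13L, n_weight = 11L, n_psych = 4L,
                           n = 59L) {
  base <- matrix(0L, n, 16); end <- matrix(0L, n, 16)
  # a stable anchor so non-switchers have a unique, constant maximum
  base[, 1] <- end[, 1] <- 1L   # QIDS1 wins Sleep unless overridden
  base[, 6] <- end[, 6] <- 1L   # QIDS6 wins Weight/appetite
  base[, 15] <- end[, 15] <- 1L # QIDS15 wins Psychomotor
  if (n_sleep > 0) { base[seq_len(n_sleep), 1] <- 3L
    end[seq_len(n_sleep), 1] <- 0L; end[seq_len(n_sleep), 2] <- 3L }
  if (n_weight > 0) { base[seq_len(n_weight), 6] <- 3L
    end[seq_len(n_weight), 6] <- 0L; end[seq_len(n_weight), 7] <- 3L }
  if (n_psych > 0) { base[seq_len(n_psych), 15] <- 3L
    end[seq_len(n_psych), 15] <- 0L; end[seq_len(n_psych), 16] <- 3L }
  rownames(base) <- rownames(end) <- sprintf("p%02d", seq_len(n))
  qids_cube(list(baseline = base, week6 = end),
            rep(c("PT", "ET"), length.out = n))
}

interaction_B <- function(res)
  res$terms$B[res$terms$term == "Time x Condition"]
interaction_p <- function(res)
  res$terms$p[res$terms$term == "Time x Condition"]
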