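# Shared fixtures: all phantoms are generated in code at test time.

no_noise <- c(PD = 0, T2 = 0, FLAIR = 0, FA = 0, MD = 0)

noiseless_spec <- function(...) {
  phantom_spec(noise_sd = no_noise, ...)
}

# A tiny ratings table: `counts[rater]` positives ("left") among the
# first subjects of `ids`, rest negative.
make_ratings <- function(counts, ids, modality = "PD", side = "left",
                         raters = paste0("R", seq_along(counts))) {
  rows <- list()
  for (k in seq_along(counts)) {
    pos <- seq_len(counts[k])
    for (i in seq_along(ids)) {
      rows[[length(rows) + 1L]] <- data.frame(
        rater_id = raters[k], subject_id = ids[i], modality = modality,
        hod_present = i %in% pos,
        side = if (i %in% pos) side else "none",
        stringsAsFactors = FALSE
      )
    }
  }
  validate_ratings(do.call(rbind, rows))
}

patient_cohort_meta <- function(ids, side = "left",
                                modalities = c("PD", "T2", "FLAIR")) {
  do.call(rbind, lapply(ids, function(id) {
    subject_meta(id, "patient", side, modalities_present = modalities)
  }))
}

control_cohort_meta <- function(ids, modalities = c("PD", "T2", "FLAIR")) {
  do.call(rbind, lapply(ids, function(id) {
    subject_meta(id, "control", "none", modalities_present = modalities)
  }))
}

# Independent brute-force Fleiss kappa: pairwise-agreement counting,
# deliberately different from the package's n_ij^2 formula.
brute_force_kappa <- function(cat_matrix) {
  # cat_matrix: N x n matrix of category labels (one column per rater)
  N <- nrow(cat_matrix); n <- ncol(cat_matrix)
  agree <- numeric(N)
  for (i in seq_len(N)) {
    pairs <- 0; hits <- 0
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        pairs <- pairs + 1
        hits <- hits + (cat_matrix[i, a] == cat_matrix[i, b])
      }
    }
    agree[i] <- hits / pairs
  }
  pbar <- mean(agree)
  marg <- table(factor(as.vector(cat_matrix))) / (N * n)
  pe <- sum(marg^2)
  if (isTRUE(all.equal(unname(pe), 1))) return(NA_real_)
  (pbar - pe) / (1 - pe)
}

# Exact two-sided Mann-Whitney p by full enumeration of which pooled
# positions belong to sample a.
brute_force_wmw_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  # two-sided: arrangements at least as extreme in |U - mu|
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
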