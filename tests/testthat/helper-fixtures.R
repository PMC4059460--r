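# shared fixtures and independent oracles

write_bg <- function(lines, file = tempfile(fileext = ".bedgraph")) {
  writeLines(lines, file)
  file
}

# exhaustive-enumeration oracle for the most probable state path:
# scores all 3^L sequences (prior x transitions x emissions) directly
viterbi_brute <- function(s, params) {
  L <- length(s)
  P <- as.matrix(expand.grid(rep(list(0:2), L)))
  lp <- log(params$state_priors)
  lA <- log(params$transition)
  sdv <- sqrt(params$vars)
  le <- sapply(1:3, function(k) dnorm(s, params$means[k], sdv[k], log = TRUE))
  le <- matrix(le, nrow = L)
  ll <- lp[P[, 1L] + 1L] + le[1L, ][P[, 1L] + 1L]
  if (L > 1L)
    for (t in 2:L)
      ll <- ll + lA[cbind(P[, t - 1L] + 1L, P[, t] + 1L)] +
        le[t, ][P[, t] + 1L]
  as.integer(P[which.max(ll), ])
}

random_hmm <- function() {
  pr <- runif(3); pr <- pr / sum(pr)
  A <- matrix(runif(9, 0.05, 1), 3, 3)
  diag(A) <- diag(A) + runif(1, 1, 20)   # diagonally dominant, gene-like
  A <- A / rowSums(A)
  structure(list(state_priors = pr, transition = A,
                 means = c(0, runif(1, -4, 4), runif(1, -4, 4)),
                 vars = c(runif(1, 1e-4, 1e-2), runif(1, 0.2, 4),
                          runif(1, 0.2, 4))),
            class = "hmm_params")
}

# small two-group experiment with one up- and one down-regulated region
small_sim <- function(seed = 11L) {
  regs <- data.frame(start = c(2000, 6000, 10000, 14000),
                     end = c(2500, 6500, 10500, 14500),
                     mu = 30, log2fc = c(0, 2, 0, -2))
  simulate_experiment(sim_config(20000L, c(5L, 5L), regs, seed = seed))
}

# minimal GTF content: two genes, three exons (1-based inclusive coords)
gtf_fixture <- function(file = tempfile(fileext = ".gtf")) {
  writeLines(c(
    paste0("chrS\ttest\texon\t101\t200\t.\t+\t.\t",
           'gene_id "G1"; exon_id "E1";'),
    paste0("chrS\ttest\texon\t301\t400\t.\t+\t.\t",
           'gene_id "G1"; exon_id "E2";'),
    paste0("chrS\ttest\texon\t1001\t1200\t.\t-\t.\t",
           'gene_id "G2"; exon_id "E3";'),
    paste0("chrS\ttest\texon\t101\t200\t.\t+\t.\t",
           'gene_id "G1"; exon_id "E1";')   # duplicate record
  ), file)
  file
}
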