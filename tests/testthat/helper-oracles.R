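# Independent brute-force oracles used to check the package's own
# implementations. These deliberately avoid the code paths they verify.

# Step-down Holm straight from the definition.
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 0
  for (k in seq_len(n)) {
    running <- max(running, (n - k + 1) * p[o[k]])
    adj[o[k]] <- min(1, running)
  }
  adj
}

# Benjamini-Hochberg straight from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(n)
  running <- Inf
  for (k in seq_along(o)) {
    rank_k <- n - k + 1
    running <- min(running, n * p[o[k]] / rank_k)
    adj[o[k]] <- min(1, running)
  }
  adj
}

# Two-sided Fisher p by full hypergeometric enumeration
# (point-probability rule).
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ])
  n2 <- sum(tab[2, ])
  k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  xs <- max(0, k - n2):min(k, m)
  probs <- dhyper(xs, m, n2, k)
  p_obs <- dhyper(x_obs, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# All-pairs Harrell's C with an explicit double loop.
oracle_harrells_c <- function(scores, time, event) {
  n <- length(scores)
  conc <- 0
  usable <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] < time[j] && event[i] == 1) {
        early <- i; late <- j
      } else if (time[j] < time[i] && event[j] == 1) {
        early <- j; late <- i
      } else if (time[i] == time[j] && xor(event[i] == 1, event[j] == 1)) {
        early <- if (event[i] == 1) i else j
        late <- if (event[i] == 1) j else i
      } else {
        next
      }
      usable <- usable + 1
      if (scores[early] > scores[late]) conc <- conc + 1
      else if (scores[early] == scores[late]) conc <- conc + 0.5
    }
  }
  conc / usable
}

# Synonymy of a single SNV by re-translating the entire mutated CDS with
# Biostrings under the vertebrate mitochondrial code.
oracle_synonymy_cds <- function(cds_ref, offset, alt_base) {
  cds_alt <- cds_ref
  substr(cds_alt, offset, offset) <- alt_base
  code <- Biostrings::getGeneticCode("2")
  tr <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       genetic.code = code,
                                       no.init.codon = TRUE))
  }
  if (tr(cds_ref) == tr(cds_alt)) "synonymous" else "non_synonymous"
}

# Exhaustive log-rank scan used as the cut-point oracle.
oracle_cut_scan <- function(scores, time, event, inner_fraction = 0.8) {
  lo <- quantile(scores, (1 - inner_fraction) / 2, names = FALSE)
  hi <- quantile(scores, 1 - (1 - inner_fraction) / 2, names = FALSE)
  cand <- sort(unique(scores[scores >= lo & scores <= hi]))
  cand <- cand[cand < max(scores)]
  data.frame(cut = cand, raw_p = vapply(cand, function(cut) {
    grp <- scores > cut
    if (sum(event[grp]) == 0 || sum(event[!grp]) == 0) return(NA_real_)
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
    pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  }, numeric(1)))
}
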