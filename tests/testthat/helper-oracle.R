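# Brute-force reference implementation of the episode/switch/TRD rules,
# written as a direct scan over prescription pairs with a transitive
# closure, deliberately sharing no code with the package internals.

oracle_episodes <- function(prescriptions, gap = 98, ad_only = FALSE) {
  p <- prescriptions
  if (ad_only) p <- p[p$drug_class == "ANTIDEPRESSANT", , drop = FALSE]
  out <- list()
  for (drug in unique(p$drug_id)) {
    days <- sort(as.numeric(p$issue_date[p$drug_id == drug] - D0))
    cls <- p$drug_class[p$drug_id == drug][1]
    k <- length(days)
    # union-find closure: i ~ j whenever |days_i - days_j| <= gap
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (abs(days[i] - days[j]) <= gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    roots <- vapply(seq_len(k), find, integer(1))
    for (r in unique(roots)) {
      d <- days[roots == r]
      out[[length(out) + 1L]] <- data.frame(
        drug_id = drug, drug_class = cls,
        start = min(d), end = max(d), n = length(d),
        duration = max(d) - min(d), stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(drug_id = character(), drug_class = character(),
                      start = numeric(), end = numeric(), n = integer(),
                      duration = numeric(), stringsAsFactors = FALSE))
  }
  eps <- do.call(rbind, out)
  eps <- eps[order(eps$start, eps$end, eps$drug_id), , drop = FALSE]
  rownames(eps) <- NULL
  eps
}

oracle_n_switches <- function(prescriptions, gap = 98, min_dur = 42,
                              overlap = 30) {
  eps <- oracle_episodes(prescriptions, gap, ad_only = TRUE)
  q <- eps[eps$duration >= min_dur, , drop = FALSE]
  q <- q[order(q$start, q$end, q$drug_id), , drop = FALSE]
  n <- 0L
  if (nrow(q) >= 2L) {
    for (i in seq_len(nrow(q) - 1L)) {
      a <- q[i, ]; b <- q[i + 1L, ]
      ovl <- min(a$end, b$end) - max(a$start, b$start)
      if (a$drug_id != b$drug_id && (b$start - a$end) <= gap &&
          ovl <= overlap) {
        n <- n + 1L
      }
    }
  }
  n
}

oracle_trd <- function(is_case, prescriptions) {
  treated <- any(prescriptions$drug_class == "ANTIDEPRESSANT")
  if (!is_case || !treated) return("NOT_APPLICABLE")
  if (oracle_n_switches(prescriptions) >= 2L) "TRD" else "NON_TRD"
}

# random mini-patient: a handful of prescriptions over a few years
random_mini_patient <- function(max_rx = 12L) {
  n <- sample(0:max_rx, 1L)
  if (n == 0L) return(no_rx())
  drugs <- c("a", "b", "c")
  out <- rx(sort(sample(0:1200, n, replace = TRUE)),
            sample(drugs, n, replace = TRUE))
  # occasionally toss in a non-antidepressant
  if (stats::runif(1) < 0.3) {
    out <- rx_bind(out, rx(sample(0:1200, 1L), "q", class = "ANTIPSYCHOTIC"))
  }
  out
}
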