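# Independent oracles, kept deliberately separate from the package internals.

# Rule-based re-derivation of the Kano evaluation table: the diagonal corners
# are questionable, "like if present" rows delight, "dislike if absent"
# columns are expected, preference for absence is reverse, the middle is
# indifferent. Written as conditionals so it cannot share code with the
# package's grid constant.
oracle_classify <- function(f, d) {
  if ((f == 1 && d == 1) || (f == 5 && d == 5)) return("Q")
  if (f == 5 || (d == 1 && f > 1)) return("R")
  if (f == 1 && d == 5) return("O")
  if (f == 1) return("A")
  if (d == 5) return("M")
  "I"
}

# Brute-force frequency row: classify each respondent one at a time.
oracle_tabulate <- function(f, d) {
  out <- c(M = 0L, O = 0L, A = 0L, I = 0L, R = 0L, Q = 0L)
  for (i in seq_along(f)) {
    tag <- oracle_classify(f[[i]], d[[i]])
    out[[tag]] <- out[[tag]] + 1L
  }
  out
}

# Cronbach's alpha via the covariance-matrix identity
# alpha = k/(k-1) * (1 - tr(C) / sum(C)).
oracle_alpha <- function(m) {
  C <- cov(as.matrix(m))
  k <- ncol(m)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# Cohen's kappa by explicit contingency accumulation.
oracle_kappa <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  n <- length(a)
  tab <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_len(n)) tab[a[[i]], b[[i]]] <- tab[a[[i]], b[[i]]] + 1
  p_o <- sum(diag(tab)) / n
  p_e <- sum((rowSums(tab) / n) * (colSums(tab) / n))
  (p_o - p_e) / (1 - p_e)
}

# Random per-item frequency rows with positive A+O+M+I mass.
random_freq_row <- function() {
  repeat {
    x <- stats::setNames(rpois(6, lambda = sample(c(1, 5, 50), 1)),
                         c("M", "O", "A", "I", "R", "Q"))
    if (sum(x[c("M", "O", "A", "I")]) > 0) return(x)
  }
}
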