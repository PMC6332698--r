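# Brute-force reference implementations, independent of the package's
# cumulative-sum kernels: every window/hexapeptide is enumerated and summed
# directly. Deliberately slow and simple.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(len, freqs = NULL) {
  paste(sample(AA, len, replace = TRUE, prob = freqs), collapse = "")
}

random_protein <- function(len, id = "fix", freqs = NULL) {
  tibble::tibble(id = id, description = "", sequence = random_sequence(len, freqs),
                 length = len)
}

# lowest index within 1e-9 of the maximum (the package's documented
# lowest-position tie-break)
oracle_argmax <- function(x) which(x >= max(x) - 1e-9)[1]

# disordered-biased residue pool (Q/N/S/G-heavy) so fixtures exercise the
# disorder gate in both directions when mixed with uniform draws
qn_freqs <- local({
  f <- rep(1, 20); names(f) <- AA
  f[c("Q", "N", "S", "G", "Y")] <- 8
  f / sum(f)
})

oracle_window_mean <- function(values, w) {
  n <- length(values) - w + 1
  vapply(seq_len(n), function(i) sum(values[i:(i + w - 1)]) / w, numeric(1))
}

oracle_foldindex <- function(seq, w) {
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
          I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
          R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
  res <- strsplit(seq, "")[[1]]
  h <- (kd[res] + 4.5) / 9
  q <- ifelse(res %in% c("K", "R"), 1, ifelse(res %in% c("D", "E"), -1, 0))
  n <- length(res) - w + 1
  vapply(seq_len(n), function(i) {
    idx <- i:(i + w - 1)
    2.785 * mean(h[idx]) - abs(mean(q[idx])) - 1.151
  }, numeric(1))
}

# composition score by direct enumeration of both averaging passes
# (symmetric-shrink second pass), including the disorder gate
oracle_composition <- function(seq, scale, w) {
  res <- strsplit(seq, "")[[1]]
  s <- scale[res]
  p <- oracle_window_mean(s, w)
  m <- length(p)
  h <- (w - 1) / 2
  q <- vapply(seq_len(m), function(j) {
    he <- min(h, j - 1, m - j)
    mean(p[(j - he):(j + he)])
  }, numeric(1))
  fi <- oracle_foldindex(seq, w)
  cand <- which(fi < 0)
  if (length(cand) == 0) {
    return(list(score = min(scale), start = NA_integer_))
  }
  best <- cand[oracle_argmax(q[cand])]
  list(score = q[best], start = best)
}

oracle_hexapeptide <- function(hex, m) {
  res <- strsplit(hex, "")[[1]]
  total <- 0
  for (i in 1:6) total <- total + m$matrix[i, res[i]]
  total
}

# amyloid core by enumerating every window and every hexapeptide within it
oracle_amyloid <- function(seq, m, core_len = 21) {
  n <- nchar(seq) - core_len + 1
  ws <- vapply(seq_len(n), function(t) {
    win <- substr(seq, t, t + core_len - 1)
    hx <- vapply(seq_len(core_len - 5), function(k) {
      oracle_hexapeptide(substr(win, k, k + 5), m)
    }, numeric(1))
    mean(hx)
  }, numeric(1))
  best <- oracle_argmax(ws)
  list(score = 100 * (ws[best] - m$anchors[1]) / (m$anchors[2] - m$anchors[1]),
       start = best)
}

# Spearman's rho from first principles: average ranks, Pearson on ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

oracle_mcc <- function(tp, fp, tn, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(den)
}

# calibration anchor panel: 21-mer cores of graded amyloidogenicity
# (Q/N/S/G -> I/V/F/Y gradient) embedded in Q/N-rich backgrounds, emulating
# an experimentally validated variant series spanning the score range
make_anchor_panel <- function(seed0, n = 20) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    frac <- (i - 1) / (n - 1)
    core <- paste(ifelse(
      withr::with_seed(seed0 + i, runif(21)) < frac,
      withr::with_seed(seed0 * 7 + i, sample(c("I", "V", "F", "Y"), 21, TRUE)),
      withr::with_seed(seed0 * 9 + i, sample(c("Q", "N", "S", "G"), 21, TRUE))),
      collapse = "")
    generate_synthetic_prld(120, seed = seed0 + i, core = core,
                            id = paste0("anchor", i))
  }))
}
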