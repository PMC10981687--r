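# Independent brute-force oracles, deliberately naive: used only to
# cross-check the package's (library-backed) implementations on tiny
# instances.

# exact two-sided Mann-Whitney by full enumeration of group assignments
bf_mann_whitney <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_stat <- function(ix) {
    a <- pooled[ix]; b <- pooled[-ix]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  obs <- u_stat(seq_len(n))
  all_ix <- utils::combn(n + m, n, simplify = FALSE)
  us <- vapply(all_ix, u_stat, numeric(1))
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Benjamini-Hochberg from the definition
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
bf_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  pr <- vapply(lo:hi, function(k)
    exp(lchoose(r1, k) + lchoose(n - r1, c1 - k) - lchoose(n, c1)),
    numeric(1))
  p_obs <- pr[a - lo + 1]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Kendall tau-b by O(n^2) pair counting with tie corrections
bf_kendall_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  n1 <- sum(vapply(table(x), function(t) t * (t - 1) / 2, numeric(1)))
  n2 <- sum(vapply(table(y), function(t) t * (t - 1) / 2, numeric(1)))
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# naive average-linkage agglomeration; returns merge heights and the
# member set created at each merge
bf_average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  sets <- list()
  while (length(groups) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in 1:(length(groups) - 1)) for (j in (i + 1):length(groups)) {
      h <- mean(d[groups[[i]], groups[[j]]])
      if (h < bh - 1e-12) { bh <- h; best <- c(i, j) }
    }
    merged <- c(groups[[best[1]]], groups[[best[2]]])
    heights <- c(heights, bh)
    sets[[length(sets) + 1]] <- sort(merged)
    groups <- c(groups[-best], list(merged))
  }
  list(heights = heights, sets = sets)
}

# per-position string scan for the three site types
bf_scan_sites <- function(utr, mirna_5p) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  s <- toupper(chartr("uU", "tT", mirna_5p))
  u <- toupper(chartr("uU", "tT", utr))
  p8 <- paste0(rc(substr(s, 2, 8)), "A")
  pm8 <- rc(substr(s, 2, 8))
  pa1 <- paste0(rc(substr(s, 2, 7)), "A")
  hits <- list()
  for (i in seq_len(max(0, nchar(u) - 6))) {
    if (i + 7 <= nchar(u) && substr(u, i, i + 7) == p8) {
      hits[[length(hits) + 1]] <- list(type = "8mer", start = i - 1)
    }
  }
  eight_starts <- vapply(hits, function(h) h$start, numeric(1))
  for (i in seq_len(nchar(u) - 6)) {
    st <- i - 1
    if (substr(u, i, i + 6) == pm8 && !(st %in% eight_starts))
      hits[[length(hits) + 1]] <- list(type = "7mer-m8", start = st)
    if (substr(u, i, i + 6) == pa1 && !((st - 1) %in% eight_starts) &&
        !(pm8 == pa1 && substr(u, i, i + 6) == pm8))
      hits[[length(hits) + 1]] <- list(type = "7mer-A1", start = st)
  }
  df <- do.call(rbind, lapply(hits, function(h)
    data.frame(site_type = h$type, start = h$start)))
  if (is.null(df)) data.frame(site_type = character(), start = integer())
  else df[order(df$start, df$site_type), , drop = FALSE]
}

# per-base overlap scan of one peak against one window (0-based half-open)
bf_overlaps <- function(p_start, p_end, w_start, w_end) {
  if (p_end <= p_start || w_end <= w_start) return(FALSE)
  any((p_start:(p_end - 1)) %in% (w_start:(w_end - 1)))
}
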