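# Brute-force statistical oracles shared by the stats and acceptance tests,
# independent of the package's own permutation code paths.

table_of <- function(ya, oa, metric = "m") {
  data.frame(subject_id = paste0("s", seq_along(c(ya, oa))),
             age_group = rep(c("YA", "OA"), c(length(ya), length(oa))),
             sex = "M", metric = metric, value = c(ya, oa))
}

brute_rank_sum_p <- function(x, y) {
  all_v <- c(x, y)
  r <- rank(all_v)
  n1 <- length(x)
  idx <- utils::combn(length(all_v), n1)
  ws <- apply(idx, 2, function(k) sum(r[k]))
  w <- sum(r[seq_len(n1)])
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}

brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  n <- length(d)
  vs <- numeric(0)
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code)[1:n])
    vs <- c(vs, sum(r[bits == 1]))
  }
  min(1, 2 * min(mean(vs <= v + 1e-9), mean(vs >= v - 1e-9)))
}

hypergeom_fisher_p <- function(m) {
  # two-sided exact p: sum of hypergeometric table probabilities <= observed
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  p_tab <- function(a) {
    b <- rs[1] - a; c_ <- cs[1] - a; d <- rs[2] - c_
    if (b < 0 || c_ < 0 || d < 0) return(NA_real_)
    exp(lchoose(rs[1], a) + lchoose(rs[2], c_) - lchoose(n, cs[1]))
  }
  amax <- min(rs[1], cs[1])
  probs <- vapply(0:amax, p_tab, 0)
  obs <- p_tab(m[1, 1])
  sum(probs[probs <= obs * (1 + 1e-7)], na.rm = TRUE)
}

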