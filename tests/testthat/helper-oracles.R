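# From-scratch reference implementations used as independent oracles.
# Deliberately naive: loops and textbook formulas only.

oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

oracle_km <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}

oracle_logrank <- function(time, event, group) {
  g1 <- unique(group)[1L]
  ts <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in ts) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g1)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# brute-force agglomeration: all pairwise cluster distances recomputed from
# the point-level distance matrix at every step; ties -> lowest index pair
oracle_agglomerate <- function(pts, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(dist(pts))
  clusters <- as.list(seq_len(nrow(pts)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        block <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        dij <- if (linkage == "complete") max(block) else mean(block)
        if (dij < best_d - 1e-12) {
          best_d <- dij; best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- clusters[-best[2L]]
    partitions[[length(partitions) + 1L]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition for label-free comparison
canon_partition <- function(labels) {
  unname(lapply(split(seq_along(labels), labels), sort))[
    order(vapply(split(seq_along(labels), labels), min, 1L))]
}

# tiny deconvolution table with an IHC vector whose true singleton mapping
# is perfectly concordant and all other cell types are anti-concordant
toy_concordant_decon <- function(n_samples = 12L, n_types = 6L, seed = 42L) {
  set.seed(seed)
  ihc <- sort(rlnorm(n_samples, 5, 1))
  scores <- matrix(NA_real_, n_types, n_samples,
                   dimnames = list(paste0("type", seq_len(n_types)),
                                   paste0("S", seq_len(n_samples))))
  scores[1L, ] <- ihc * 1e-3
  for (i in 2:n_types) scores[i, ] <- rev(ihc) * 1e-3 + runif(n_samples, 0, 1e-4)
  list(decon = deconvolution_result(scores, "toy", "arbitrary"),
       ihc = setNames(ihc, colnames(scores)),
       mapping = composite_mapping("toy", list(M = "type1"), rownames(scores)))
}

# drop class/tag attributes, keep dim+dimnames, for value-only comparisons
strip_attrs <- function(x) {
  y <- unclass(x)
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  y
}
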