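# Independent brute-force oracles used to freeze expected values. Each is
# deliberately written from the definition, not from the implementation it
# checks.

# exact one-sided signed-rank p-value by enumerating all sign patterns
enumerate_signed_rank_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, 0)
  switch(alternative,
         greater = mean(ws >= w_obs),
         less = mean(ws <= w_obs),
         two.sided = min(1, 2 * min(mean(ws >= w_obs), mean(ws <= w_obs))))
}

# exact one-sided rank-sum p-value by enumerating group assignments
enumerate_rank_sum_p <- function(x, y, alternative = "greater") {
  all_v <- c(x, y)
  n <- length(all_v); nx <- length(x)
  r <- rank(all_v)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  switch(alternative,
         greater = mean(us >= u_obs),
         less = mean(us <= u_obs))
}

# Ward2 (distance-input, Murtagh-Legendre) agglomeration via the
# Lance-Williams recurrence on squared dissimilarities
lance_williams_ward2 <- function(X) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  diag(D2) <- Inf
  sizes <- rep(1, n)
  id <- -(1:n)                      # hclust singleton convention
  alive <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2); height <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    idx <- which(alive)
    sub <- D2[idx, idx, drop = FALSE]
    k <- arrayInd(which.min(sub), dim(sub))
    i <- idx[min(k)]; j <- idx[max(k)]
    height[s] <- sqrt(D2[i, j])
    merge[s, ] <- sort(c(id[i], id[j]))
    ni <- sizes[i]; nj <- sizes[j]
    for (k2 in which(alive)) {
      if (k2 == i || k2 == j) next
      nk <- sizes[k2]
      D2[i, k2] <- D2[k2, i] <-
        ((ni + nk) * D2[i, k2] + (nj + nk) * D2[j, k2] - nk * D2[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    alive[j] <- FALSE
    id[i] <- s
  }
  list(merge = merge, height = height)
}

# exact minimal set cover size by depth-first search with pruning
min_cover_size_dfs <- function(cover_sets, universe) {
  candidates <- sort(unique(unlist(cover_sets)))
  covers <- lapply(candidates, function(d) {
    which(vapply(seq_along(universe), function(i) d %in% cover_sets[[i]], TRUE))
  })
  best <- length(universe) + 1L
  recurse <- function(uncovered, depth) {
    if (!length(uncovered)) { best <<- min(best, depth); return() }
    if (depth + 1L >= best) return()
    target <- uncovered[1]
    for (ci in seq_along(candidates)) {
      if (target %in% covers[[ci]]) {
        recurse(setdiff(uncovered, covers[[ci]]), depth + 1L)
      }
    }
  }
  recurse(seq_along(universe), 0L)
  best
}

# analytic thickness of the shell between two confocal-offset ellipsoids
# along the mid-wall normal through a point
ellipsoid_shell_thickness <- function(p, a_en, c_en, t) {
  a_mid <- a_en + t / 2; c_mid <- c_en + t / 2
  d <- c(p[1] / a_mid^2, p[2] / a_mid^2, p[3] / c_mid^2)
  d <- d / sqrt(sum(d^2))
  hit <- function(a, cc) {
    A <- (d[1]^2 + d[2]^2) / a^2 + d[3]^2 / cc^2
    B <- 2 * ((p[1] * d[1] + p[2] * d[2]) / a^2 + p[3] * d[3] / cc^2)
    C <- (p[1]^2 + p[2]^2) / a^2 + p[3]^2 / cc^2 - 1
    disc <- B^2 - 4 * A * C
    if (disc < 0) return(NA_real_)
    (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  s_en <- hit(a_en, c_en)       # inner surface: want the root behind p
  s_ep <- hit(a_en + t, c_en + t)
  s_in <- max(s_en[s_en <= 0])
  s_out <- min(s_ep[s_ep >= 0])
  s_out - s_in
}
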