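# Independent oracles and shared fixtures for the test suite.

# Naive FIFO breadth-first search over the hex lattice; deliberately a
# different algorithm from distance_field() so it can stand as its oracle.
bfs_dist_oracle <- function(grid, targets) {
  dist <- rep(Inf, grid$n_cells)
  dist[targets] <- 0
  queue <- as.integer(targets)
  head <- 1L
  while (head <= length(queue)) {
    c0 <- queue[head]
    head <- head + 1L
    for (nb in hex_neighbors(grid, c0)) {
      if (!is.na(nb) && dist[nb] > dist[c0] + 1) {
        dist[nb] <- dist[c0] + 1
        queue <- c(queue, nb)
      }
    }
  }
  dist
}

# Two-parameter Bernoulli-likelihood maximiser by iterated grid refinement;
# never calls glm.
grid_logit_oracle <- function(x, y, span = 20, steps = 41L, refinements = 14L) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  c0 <- 0; c1 <- 0; half <- span
  for (r in seq_len(refinements)) {
    b0s <- seq(c0 - half, c0 + half, length.out = steps)
    b1s <- seq(c1 - half, c1 + half, length.out = steps)
    vals <- outer(b0s, b1s, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    c0 <- b0s[best[1]]; c1 <- b1s[best[2]]
    # shrink gently so the maximiser can track the likelihood ridge
    half <- half * 0.35
  }
  c(b0 = c0, b1 = c1)
}

# Trapezoidal integration of the empirical ROC curve (tied scores grouped).
auc_trapezoid_oracle <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(y, grp, sum)
  fp <- tapply(1 - y, grp, sum)
  ctp <- c(0, cumsum(tp)); cfp <- c(0, cumsum(fp))
  tpr <- ctp / sum(y); fpr <- cfp / sum(1 - y)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

tiny_grid <- function(w = 1200, h = 1200, s = 10) build_grid(w, h, s)

tiny_packed <- function(seed = 7) {
  generate_landscape("packed", tiny_grid(), seed = seed, cluster_area_m2 = 2.5e5)
}

tiny_rain <- function(n_days = 800, seed = 3) generate_rainfall(n_days, seed = seed)

# quiet params: nothing moves, nothing dies, nothing dries out
frozen_params <- function(...) {
  ibm_params(mort_egg = 0, mort_tadpole = 0, mort_metamorph = 0,
             mort_juvenile = 0, mort_adult = 0, daily_water_loss_frac = 0,
             move_scale_wet_m = 0, move_scale_dry_m = 0, ...)
}

# inject a clutch directly into a sim state (internal layout)
add_clutch <- function(state, cell, n, age = 0L, meta_age = 45L, stage = 1L) {
  state$clutches$cell <- c(state$clutches$cell, as.integer(cell))
  state$clutches$n <- c(state$clutches$n, as.integer(n))
  state$clutches$age <- c(state$clutches$age, as.integer(age))
  state$clutches$meta_age <- c(state$clutches$meta_age, as.integer(meta_age))
  state$clutches$stage <- c(state$clutches$stage, as.integer(stage))
  state$clutches$mother <- c(state$clutches$mother, 0L)
  state
}
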