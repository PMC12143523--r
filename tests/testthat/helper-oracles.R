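# Independent brute-force oracles used to cross-check the implementations.
# These deliberately use naive formulations (explicit loops, full matrix
# inversions) and share no code with the package internals.

# Great-circle distance via the spherical law of cosines, same sphere.
oracle_haversine <- function(lat1, lon1, lat2, lon2, R = 6371) {
  r <- pi / 180
  ca <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  R * acos(pmin(pmax(ca, -1), 1))
}

# Pairwise genetic distance by double loop.
oracle_distance_matrix <- function(V) {
  n <- nrow(V)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(V[i, ]) & !is.na(V[j, ])
    D[i, j] <- if (any(ok)) mean(abs(V[i, ok] - V[j, ok])) else NaN
  }
  D
}

# NN prediction by full sort of the distance vector (ties at 1e-9
# resolution break by training order, the shared convention).
oracle_nn <- function(V, samples, testIdx, k) {
  d <- sapply(seq_len(nrow(V)), function(j) {
    if (j == testIdx) return(Inf)
    ok <- !is.na(V[testIdx, ]) & !is.na(V[j, ])
    mean(abs(V[testIdx, ok] - V[j, ok]))
  })
  nb <- order(round(d, 9))[seq_len(k)]
  c(lat = mean(samples$lat[nb]), lon = mean(samples$lon[nb]))
}

# Exact GP posterior with explicit matrix inversion (RBF kernel, zero mean
# on pre-standardised targets, unit signal variance).
oracle_gp_posterior <- function(Xtr, ys, Xte, l, noise) {
  k <- function(a, b) exp(-sum((a - b)^2) / (2 * l^2))
  n <- nrow(Xtr); m <- nrow(Xte)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) K[i, j] <- k(Xtr[i, ], Xtr[j, ])
  Ks <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n) Ks[i, j] <- k(Xte[i, ], Xtr[j, ])
  A <- solve(K + diag(noise, n))
  mean <- Ks %*% A %*% ys
  var <- sapply(1:m, function(i) 1 - Ks[i, ] %*% A %*% Ks[i, ])
  list(mean = drop(mean), sd = sqrt(pmax(drop(var), 0)))
}

# Generalised least squares / BLUP oracle: y = 1 mu + g + e with
# Var(y) = s2g K + s2e I, everything by explicit solve().
oracle_gblup <- function(K, y, s2g, s2e) {
  t <- which(!is.na(y)); u <- which(is.na(y))
  Vt <- s2g * K[t, t] + s2e * diag(length(t))
  Vi <- solve(Vt)
  one <- rep(1, length(t))
  mu <- drop((t(one) %*% Vi %*% y[t]) / (t(one) %*% Vi %*% one))
  W <- s2g * K[t, u, drop = FALSE]
  pred <- mu + drop(t(W) %*% Vi %*% (y[t] - mu))
  pev <- sapply(seq_along(u), function(i) {
    w <- W[, i]
    d <- 1 - drop(t(one) %*% Vi %*% w)
    s2g * K[u[i], u[i]] - drop(t(w) %*% Vi %*% w) +
      d^2 / drop(t(one) %*% Vi %*% one)
  })
  list(pred = pred, pev = pev, mu = mu)
}

# Exhaustive HWE scorer over cells.
oracle_grid_argmax <- function(freq, g, ploidy) {
  scores <- apply(freq, 1, function(p) {
    ll <- 0
    for (j in seq_along(g)) {
      if (is.na(g[j])) next
      pj <- unname(p[j])
      if (ploidy[j] == "plastid") {
        ll <- ll + log(if (g[j] == 1) pj else 1 - pj)
      } else {
        pr <- c(`0` = (1 - pj)^2, `0.5` = 2 * pj * (1 - pj), `1` = pj^2)
        ll <- ll + log(pr[[as.character(g[j])]])
      }
    }
    ll
  })
  list(idx = which.max(scores), scores = scores)
}
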