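# shared fixtures, built in code

# simple unconstrained 2-D space
space_2d <- function(gp = 5L) {
  design_space(list(ds_variable("a", 0, 1, grid_points = gp),
                    ds_variable("b", 0, 10, grid_points = gp)))
}

# ammonia-lyase-like 3-variable space with the solubility constraint
space_constrained <- function(gp = 6L) {
  design_space(
    list(ds_variable("NH4", 1, 6, "M", grid_points = gp),
         ds_variable("DMSO", 5, 30, "%", grid_points = gp),
         ds_variable("enzyme", 1, 20, "uM", grid_points = gp)),
    list(linear_constraint(c(NH4 = 28.6, DMSO = 2, enzyme = 2.1), 200)))
}

# a candidate set with an identity scaler, for tests phrased in z-units
zunit_candidates <- function(points) {
  pts <- as.matrix(points)
  if (is.null(colnames(pts))) colnames(pts) <- paste0("x", seq_len(ncol(pts)))
  scaler <- list(mean = rep(0, ncol(pts)), sd = rep(1, ncol(pts)))
  structure(list(points = pts, standardized = pts, scaler = scaler,
                 space = NULL),
            class = "candidate_set")
}

# ledger with measured observations at given points/values
measured_ledger <- function(space, points, values, fom = "TON") {
  led <- ledger_append(new_ledger(space, fom = fom), as.matrix(points),
                       stats::setNames(list(values), fom),
                       iteration = 0L, source = "measured")
  led
}

# independent dense-solve GP posterior oracle (Matern 5/2, zero mean),
# written directly from the textbook formulas with solve(), not chol
gp_posterior_oracle <- function(X, y, Xnew, ell, s2, noise) {
  kern <- function(A, B) {
    K <- matrix(0, nrow(A), nrow(B))
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      r <- sqrt(sum(((A[i, ] - B[j, ]) / ell)^2))
      K[i, j] <- s2 * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
    }
    K
  }
  K <- kern(X, X) + diag(noise, nrow(X))
  Ks <- kern(Xnew, X)
  Kinv <- solve(K)
  mu <- Ks %*% Kinv %*% y
  var <- s2 - diag(Ks %*% Kinv %*% t(Ks))
  list(mean = drop(mu), sd = sqrt(pmax(var, 0)))
}
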