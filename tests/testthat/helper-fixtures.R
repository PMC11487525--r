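# Shared fixtures (memoised: training is the expensive step) and the
# independent spectral-radius oracle used against measure_spectral_radius().

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, maker) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- maker()
  .fixtures[[key]]
}

# a well-separated task (x_cen = 8) trained at rho = 0.2 with a short
# training window: reconstructs both orbits to sub-percent radial error
trained_good <- function() fixture("good", function() {
  train_seeing_double(reservoir_realization(0.2, seed = 7),
                      rc_params(), task_pair(8), train_config(20, 120))
})

# same setup with linear-only features (admits mirror attractors)
trained_linear <- function() fixture("linear", function() {
  train_seeing_double(reservoir_realization(0.2, seed = 7),
                      rc_params(), task_pair(8), train_config(20, 120),
                      features = "linear")
})

# a realization/config whose closed loop switches between the two
# metastable orbit regions (x_cen = 6.5, full training window)
trained_switching <- function() fixture("switching", function() {
  train_seeing_double(reservoir_realization(0.25, seed = 1),
                      rc_params(), task_pair(6.5), train_config())
})

# independent spectral-radius oracle: real Schur form, eigenvalues read
# off the 1x1 / 2x2 diagonal blocks in closed form
schur_radius <- function(m) {
  s <- Matrix::Schur(Matrix::Matrix(m), vectors = FALSE)
  Tm <- as.matrix(s$T)
  n <- nrow(Tm)
  vals <- numeric(0)
  i <- 1
  while (i <= n) {
    if (i < n && abs(Tm[i + 1, i]) > 0) {
      blk <- Tm[i:(i + 1), i:(i + 1)]
      tr <- blk[1, 1] + blk[2, 2]
      de <- blk[1, 1] * blk[2, 2] - blk[1, 2] * blk[2, 1]
      disc <- tr^2 - 4 * de
      vals <- c(vals, if (disc < 0) rep(sqrt(de), 2) else
        abs(c(tr + sqrt(disc), tr - sqrt(disc)) / 2))
      i <- i + 2
    } else {
      vals <- c(vals, abs(Tm[i, i]))
      i <- i + 1
    }
  }
  max(vals)
}

# brute-force ridge oracle: generic solve() of the normal equations
ridge_oracle <- function(X, Y, beta) {
  Y %*% t(X) %*% solve(tcrossprod(X) + beta * diag(nrow(X)))
}

# zero-adjacency realization (rho = 0) for linear-decay benchmarks
zero_realization <- function(n_nodes = 10) {
  reservoir_realization(0, seed = 11, n_nodes = n_nodes)
}

zero_input <- function(t) cbind(rep(0, length(t)), rep(0, length(t)))
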