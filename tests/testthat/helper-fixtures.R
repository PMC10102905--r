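# Shared fixtures.  MCMC fits are cached per session so several test files
# can interrogate one small fit without refitting.

quickSpec <- function(K = 2, draws = 150, warmup = 300, adapt = 200,
                      seed = 33, ...) {
  mcModelSpec(K = K, drawsPerChain = draws, warmup = warmup, adapt = adapt,
              seed = seed, ...)
}

.fixtureEnv <- new.env(parent = emptyenv())

# one small simulated panel + fitted model + imputed counterfactuals
smallFit <- function() {
  if (is.null(.fixtureEnv$small)) {
    sim <- simulatePanel(simConfig(S = 1, N = 20, nTreated = 6, seed = 401), 1)
    fit <- suppressWarnings(fitMCModel(sim$panel, quickSpec(seed = 401)))
    cf <- imputeCounterfactuals(fit, seed = 402)
    .fixtureEnv$small <- list(sim = sim, fit = fit, cf = cf)
  }
  .fixtureEnv$small
}

# a hand-built panel: nTreated treated rows (mask in final column)
toyPanel <- function(N = 4, T = 10, nTreated = 1, counts = NULL,
                     pop = 1000) {
  ids <- sprintf("C%02d", seq_len(N))
  if (is.null(counts))
    counts <- matrix(10L, N, T)
  dimnames(counts) <- list(ids, paste0("I", seq_len(T)))
  D <- matrix(0, N, T, dimnames = dimnames(counts))
  if (nTreated > 0) D[seq_len(nTreated), T] <- 1
  offs <- matrix(pop, N, T, dimnames = dimnames(counts))
  stormPanel(counts, D, offs, stormId = "TOY", T0 = T)
}

# hand-built MCFit with fixed parameter draws (no MCMC), Poisson likelihood
constantFit <- function(panel, alpha, M = 50) {
  N <- nrow(panel); T <- ncol(panel)
  methods::new("MCFit",
    panel = panel,
    spec = mcModelSpec(K = 0, likelihood = "poisson", chains = 2,
                       drawsPerChain = M / 2),
    alpha = rep(alpha, M),
    gamma = matrix(0, M, N), psi = matrix(0, M, T),
    U = array(0, c(M, N, 0)), V = array(0, c(M, T, 0)),
    phi = numeric(), chain = rep(1:2, each = M / 2),
    diagnostics = list())
}

# hand-built CounterfactualDraws for estimand arithmetic tests
manualDraws <- function(Y0, cells, stormId = "TOY") {
  methods::new("CounterfactualDraws", Y0 = Y0, cells = cells,
               stormId = stormId)
}
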