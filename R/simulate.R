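# Synthetic flow-cytometry generator.
#
# Minimal generative model reproducing the statistical structure of
# heterogeneous cytokine signalling: lognormal expression heterogeneity, a
# saturating Hill dose-response, negative feedback attenuating the late
# response, an additive background noise floor, and multiplicative lognormal
# measurement noise on both channels.  The multiplicative-expression /
# additive-floor structure is the minimal model with dose-dependent
# expression-response coupling: at low dose the background dominates and the
# response is nearly independent of expression, at saturating dose the
# response is nearly proportional to expression (a pure multiplicative model
# would make that coupling dose-invariant).

#' Configuration for the synthetic single-cell generator
#'
#' Scenario modifiers are pure parameter transforms applied when the
#' configuration is resolved, never branches in the sampling code:
#' \itemize{
#'   \item \code{"MEF"}: baseline parameters as given.
#'   \item \code{"STAT3high"}: \code{expression_mu + ln(3)} (3-fold mean
#'     overexpression).
#'   \item \code{"SOCS3ko"}: \code{feedback_phi = 0} (no late feedback).
#'   \item \code{"S727Ahigh"}: overexpression as STAT3high plus response gain
#'     \code{beta * gain_factor} (hyper-phosphorylation).
#' }
#'
#' @param n_cells cells per (dose, replicate) condition (default 10000, the
#'   conventional flow-cytometry acquisition per condition).
#' @param doses dose levels in ng/ml, 0 = unstimulated.  The default 12-level
#'   grid spans 0-200 ng/ml with saturation near 25 ng/ml.
#' @param n_replicates independent replicate experiments.
#' @param expression_mu,expression_sigma lognormal (natural-log) parameters
#'   of latent expression.
#' @param beta response per unit expression at dose saturation (before
#'   capacity saturation).
#' @param cap_esat phosphorylation-capacity scale: the response saturates in
#'   expression as \eqn{E/(1 + E/E_{sat})}, emulating the finite amount of
#'   activated receptor/JAK complexes available to phosphorylate STAT3.
#'   \code{Inf} disables the saturation (purely multiplicative coupling).
#' @param hill_K half-saturation dose (ng/ml).
#' @param hill_n Hill coefficient.
#' @param sigma_b additive background noise sd (response units).
#' @param meas_sigma multiplicative lognormal measurement noise sd (log10
#'   units), applied to both observed channels.
#' @param feedback_phi feedback attenuation strength at the late time point.
#' @param gain_factor response-gain multiplier of the S727Ahigh scenario.
#' @param scenario one of \code{"MEF"}, \code{"STAT3high"}, \code{"SOCS3ko"},
#'   \code{"S727Ahigh"}.
#' @param time minutes post-stimulation, 15 (early) or 90 (late; feedback
#'   active in scenarios with intact feedback).
#' @param seed integer seed; the generator splits deterministic sub-streams
#'   per (replicate, dose), so adding a dose level does not perturb others.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_cells = 10000L,
                       doses = c(0, 0.5, 1, 2.5, 5, 10, 15, 25, 50, 75, 100, 200),
                       n_replicates = 3L,
                       expression_mu = log(100),
                       expression_sigma = 0.5,
                       beta = 1,
                       cap_esat = 150,
                       hill_K = 10,
                       hill_n = 1.5,
                       sigma_b = 20,
                       meas_sigma = 0.05,
                       feedback_phi = 2,
                       gain_factor = 1.8,
                       scenario = c("MEF", "STAT3high", "SOCS3ko", "S727Ahigh"),
                       time = 15,
                       seed = 1L) {
  scenario <- match.arg(scenario)
  cfg <- list(n_cells = as.integer(n_cells), doses = as.numeric(doses),
              n_replicates = as.integer(n_replicates),
              expression_mu = expression_mu,
              expression_sigma = expression_sigma,
              beta = beta, cap_esat = cap_esat,
              hill_K = hill_K, hill_n = hill_n,
              sigma_b = sigma_b, meas_sigma = meas_sigma,
              feedback_phi = feedback_phi, gain_factor = gain_factor,
              scenario = scenario, time = time, seed = as.integer(seed))
  with(cfg, {
    if (n_cells < 1L || n_replicates < 1L)
      stop("parameter error: n_cells and n_replicates must be >= 1",
           call. = FALSE)
    if (any(doses < 0) || !length(doses))
      stop("parameter error: doses must be >= 0", call. = FALSE)
    if (expression_sigma <= 0 || beta <= 0 || cap_esat <= 0 ||
        hill_K <= 0 || hill_n <= 0 ||
        sigma_b <= 0 || meas_sigma <= 0)
      stop("parameter error: scale parameters must be > 0", call. = FALSE)
    if (!time %in% c(15, 90))
      stop("parameter error: time must be 15 or 90 minutes", call. = FALSE)
  })
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s @ %g min | %d doses x %d replicates x %d cells | seed %d\n",
              x$scenario, x$time, length(x$doses), x$n_replicates, x$n_cells,
              x$seed))
  invisible(x)
}

# scenario -> effective parameters; pure transforms, no sampling branches
resolve_scenario <- function(cfg) {
  p <- cfg
  if (cfg$scenario %in% c("STAT3high", "S727Ahigh"))
    p$expression_mu <- cfg$expression_mu + log(3)
  if (cfg$scenario == "S727Ahigh")
    p$beta <- cfg$beta * cfg$gain_factor
  if (cfg$scenario == "SOCS3ko")
    p$feedback_phi <- 0
  p
}

hill_response <- function(d, K, n) ifelse(d > 0, d^n / (d^n + K^n), 0)

# deterministic per-(replicate, dose) stream seed, kept below 2^31
stream_seed <- function(seed, replicate, dose) {
  (seed %% 65536L) * 32749 + replicate * 7919 +
    (round(dose * 100) %% 65536) * 31 %% .Machine$integer.max
}

#' Simulate a heterogeneous single-cell dose-response dataset
#'
#' For each cell i at dose d:
#' \deqn{E_i \sim LogNormal(\mu, \sigma);\quad
#'       h(d) = d^{n}/(d^{n} + K^{n});\quad
#'       \kappa = 1/(1 + \phi h(d)) \textrm{ at } t = 90}
#' noiseless response \eqn{P_i = \beta \tilde{E}_i h(d) \kappa} with
#' \eqn{\tilde{E}_i = E_i/(1 + E_i/E_{sat})} (saturable phosphorylation
#' capacity; at overexpressed levels extra protein is phosphorylated less
#' efficiently, which weakens the expression-response coupling); observed
#' response
#' \eqn{R_i = (P_i + \epsilon_b) 10^{\epsilon_m}} with the additive noise
#' truncated at \eqn{-P_i} (non-negativity); observed expression
#' \eqn{E_i 10^{\epsilon_m'}}.  Feedback applies only at t = 90 in scenarios
#' with intact feedback (\code{feedback_phi > 0}).
#'
#' @param config a \code{\link{sim_config}}.
#' @return A \code{cell_table} with \code{n_cells * length(doses) *
#'   n_replicates} rows.  Attribute \code{ground_truth} is a data frame with
#'   the latent expression \code{E}, the noiseless response \code{P} and the
#'   per-dataset \code{true_dependency} flag; it is for validation only and
#'   is never consumed by the estimators.
#' @examples
#' cfg <- sim_config(n_cells = 200, n_replicates = 1, seed = 7)
#' cells <- simulate_cells(cfg)
#' print(cells)
#' @export
simulate_cells <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("parameter error: config must be a sim_config", call. = FALSE)
  p <- resolve_scenario(config)
  kap_active <- p$time == 90 && p$feedback_phi > 0
  chunks <- vector("list", p$n_replicates * length(p$doses))
  gt <- vector("list", length(chunks))
  k <- 0L
  for (r in seq_len(p$n_replicates)) for (d in p$doses) {
    k <- k + 1L
    set.seed(stream_seed(p$seed, r, d))
    E <- rlnorm(p$n_cells, p$expression_mu, p$expression_sigma)
    h <- hill_response(d, p$hill_K, p$hill_n)
    kap <- if (kap_active) 1 / (1 + p$feedback_phi * h) else 1
    E_eff <- if (is.finite(p$cap_esat)) E / (1 + E / p$cap_esat) else E
    P <- p$beta * E_eff * h * kap
    eb <- pmax(rnorm(p$n_cells, 0, p$sigma_b), -P)  # truncated at -P
    R <- (P + eb) * 10^rnorm(p$n_cells, 0, p$meas_sigma)
    E_obs <- E * 10^rnorm(p$n_cells, 0, p$meas_sigma)
    chunks[[k]] <- data.frame(expression = E_obs, response = R,
                              dose = d, time = p$time,
                              replicate = as.character(r),
                              line = config$scenario,
                              stringsAsFactors = FALSE)
    gt[[k]] <- data.frame(E = E, P = P, dose = d,
                          replicate = as.character(r))
  }
  out <- do.call(rbind, chunks)
  class(out) <- c("cell_table", "data.frame")
  truth <- do.call(rbind, gt)
  attr(truth, "true_dependency") <- p$beta * p$expression_sigma > 0
  attr(out, "ground_truth") <- truth
  attr(out, "config") <- config
  out
}

H2 <- function(p) ifelse(p %in% c(0, 1), 0, -p * log2(p) - (1 - p) * log2(1 - p))

#' Analytic reference channels and samples
#'
#' Exact fixtures for validating the capacity and MI estimators:
#' \code{"bsc"} (binary symmetric channel, capacity \code{1 - H2(p)}),
#' \code{"identity"} (noiseless k-ary channel, capacity \code{log2(k)}),
#' \code{"erasure"} (binary erasure channel, capacity \code{1 - p}) and
#' \code{"gaussian_pair"} (n paired draws with correlation rho, MI
#' \code{-1/2 log2(1 - rho^2)}).
#'
#' @param kind channel kind.
#' @param p crossover / erasure probability in [0, 1].
#' @param k alphabet size for the identity channel.
#' @param rho,n,seed correlation, sample size and seed for
#'   \code{"gaussian_pair"}.
#' @return A \code{discrete_channel}, or for \code{"gaussian_pair"} a data
#'   frame with columns \code{x}, \code{y}.
#' @export
make_reference_channel <- function(kind = c("bsc", "identity", "erasure",
                                            "gaussian_pair"),
                                   p = 0.1, k = 2L, rho = 0.5,
                                   n = 1000L, seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    bsc = {
      if (p < 0 || p > 1) stop("parameter error: p in [0,1]", call. = FALSE)
      new_discrete_channel(matrix(c(1 - p, p, p, 1 - p), 2, 2, byrow = TRUE),
                           inputs = c(0, 1))
    },
    identity = {
      if (k < 2L) stop("parameter error: k >= 2", call. = FALSE)
      new_discrete_channel(diag(k), inputs = seq_len(k))
    },
    erasure = {
      if (p < 0 || p > 1) stop("parameter error: p in [0,1]", call. = FALSE)
      new_discrete_channel(matrix(c(1 - p, p, 0,
                                    0, p, 1 - p), 2, 3, byrow = TRUE),
                           inputs = c(0, 1))
    },
    gaussian_pair = {
      if (abs(rho) >= 1) stop("parameter error: |rho| < 1", call. = FALSE)
      set.seed(seed)
      x <- rnorm(n)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
      data.frame(x = x, y = y)
    })
}

#' Write a cell_table fixture to CSV or FCS
#'
#' CSV fixtures round-trip exactly through \code{\link{load_cells}}.  FCS
#' fixtures are minimal FCS 3.1 list-mode float files with channels
#' \code{STAT3} (expression) and \code{pSTAT3} (response) plus a JSON sidecar
#' \code{<path>.json} carrying dose/time/replicate/line; they round-trip to
#' float32 precision.
#'
#' @param cells a \code{cell_table} (for FCS: one condition, i.e. one
#'   (dose, time, replicate, line) stratum).
#' @param path output path.
#' @param format \code{"csv"} or \code{"fcs"}.
#' @return \code{path}, invisibly.
#' @export
write_fixture <- function(cells, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  validate_cell_table(cells)
  if (format == "csv") {
    write_cells(cells, path)
  } else {
    strata <- unique(cells[, c("dose", "time", "replicate", "line")])
    if (nrow(strata) != 1L)
      stop("parameter error: FCS fixtures hold one condition per file",
           call. = FALSE)
    mat <- cbind(STAT3 = cells$expression, pSTAT3 = cells$response)
    write_fcs(mat, path)
    jsonlite::write_json(as.list(strata), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
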