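#' Energy model: scalarized objectives plus humanness prior
#'
#' Defines the Boltzmann target
#' `p(x) = (1/Z) p_HUM(x) exp(-E(x) / T)` with the linear scalarization
#' `E(x) = -sum_i w_i f_i(x)`, where the `f_i` are the design objectives to
#' be maximized (canonically the affinity acquisition and the solubility
#' score: `E = -w f_aff - (1-w) f_sol`). Property values are memoized per
#' sequence because samplers revisit states and the GP posterior is the
#' expensive term.
#'
#' @param properties Named list of objective functions `sequence -> real`
#'   (higher = better).
#' @param weights Non-negative weights summing to 1, one per property.
#' @param T_inv Inverse temperature `1/T > 0` (user-facing; typical values
#'   10-30). Higher values concentrate the distribution on low energies.
#' @param prior An [ar_prior()]; defaults to uniform, in which case the
#'   target reduces to the maximum-entropy Boltzmann form.
#' @param memoize Cache property evaluations per sequence.
#' @return Object of class `energy_model`.
#' @export
energy_model <- function(properties, weights, T_inv = 10,
                         prior = uniform_prior(), memoize = TRUE) {
  stopifnot(is.list(properties), length(properties) >= 1L,
            all(vapply(properties, is.function, logical(1))))
  if (length(weights) != length(properties))
    stop("one weight per property required", call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("weights must be >= 0 and sum to 1", call. = FALSE)
  if (T_inv <= 0) stop("T_inv must be > 0", call. = FALSE)
  if (is.null(names(properties)))
    names(properties) <- sprintf("f%d", seq_along(properties))
  structure(list(properties = properties, weights = weights, T_inv = T_inv,
                 prior = prior,
                 cache = if (memoize) new.env(parent = emptyenv()) else NULL),
            class = "energy_model")
}

# Evaluate all property functions at x (memoized).
property_values <- function(m, x) {
  if (!is.null(m$cache) && exists(x, m$cache, inherits = FALSE))
    return(get(x, m$cache, inherits = FALSE))
  v <- vapply(names(m$properties), function(nm) {
    val <- tryCatch(m$properties[[nm]](x), error = function(e)
      stop("property '", nm, "' failed on '", x, "': ", conditionMessage(e),
           call. = FALSE))
    as.numeric(val)
  }, numeric(1))
  if (!is.null(m$cache)) assign(x, v, m$cache)
  v
}

#' Scalarized energy of a sequence
#'
#' `E(x) = -sum_i w_i f_i(x)`; lower energy means better objectives.
#'
#' @param m An [energy_model()].
#' @param x Amino-acid string.
#' @return Scalar energy.
#' @export
energy <- function(m, x) {
  -sum(m$weights * property_values(m, x))
}

#' Log unnormalized Boltzmann density
#'
#' `ln p_HUM(x) - E(x) / T`. The partition function is never computed:
#' samplers only use density ratios.
#'
#' @inheritParams energy
#' @return Scalar log unnormalized density.
#' @export
log_unnorm_density <- function(m, x) {
  prior_logp(m$prior, x) - m$T_inv * energy(m, x)
}

#' Two-objective energy model for affinity and solubility
#'
#' Convenience constructor for the canonical configuration
#' `E(x) = -w f_aff(x; beta) - (1-w) f_sol(x)`, with the acquisition
#' coefficient `beta` folded into the affinity property.
#'
#' @param gp A fitted [gp_model()].
#' @param enc Encoder used for GP queries (default the registered one-hot).
#' @param beta Acquisition coefficient for [gp_acquisition()].
#' @param w Affinity weight in `[0, 1]`; solubility gets `1 - w`.
#' @param sasa,hw,const Passed to [solubility_score()].
#' @inheritParams energy_model
#' @return An [energy_model()] with properties `aff` and `sol`.
#' @export
affinity_solubility_model <- function(gp, enc = get_encoder("onehot"),
                                      beta = 0, w = 0.85, T_inv = 10,
                                      prior = uniform_prior(),
                                      sasa = sasa_provider("constant"),
                                      hw = hydrophobicity_weights(),
                                      const = 0) {
  stopifnot(w >= 0, w <= 1)
  energy_model(
    properties = list(
      aff = function(x) gp_acquisition(gp, enc$encode(x), beta = beta),
      sol = function(x) solubility_score(x, sasa = sasa, hw = hw,
                                         const = const)),
    weights = c(w, 1 - w), T_inv = T_inv, prior = prior)
}
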