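#' Generate a deterministic family of perturbed test networks
#'
#' Produces anatomical variants of the reference Circle of Willis for
#' property-style testing: every segment diameter is multiplied by an
#' independent factor drawn uniformly from
#' \eqn{[1-\mathrm{perturbation}, 1+\mathrm{perturbation}]}, and,
#' optionally, one communicating vessel (ACoA or one PCoA) is removed —
#' the common incomplete-circle variants. Generation is deterministic
#' given `seed`; the caller's RNG state is left untouched. Every fixture
#' passes [validate_topology()].
#'
#' @param seed integer seed for the fixture stream.
#' @param count number of networks to generate.
#' @param perturbation half-width of the diameter-factor interval, in
#'   \eqn{[0, 0.5)}; `0` returns `count` copies of the reference network.
#' @param remove_prob probability that a fixture loses one communicating
#'   vessel (default 0, keeping the circle complete).
#' @return A list of `cow_network` objects.
#' @examples
#' nets <- generate_fixture_networks(seed = 1, count = 3,
#'                                   perturbation = 0.1)
#' @export
generate_fixture_networks <- function(seed, count = 10, perturbation = 0.1,
                                      remove_prob = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            is.numeric(count), count >= 1,
            is.numeric(perturbation),
            is.numeric(remove_prob), remove_prob >= 0, remove_prob <= 1)
  if (perturbation < 0 || perturbation >= 0.5)
    stop("perturbation must lie in [0, 0.5)", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  ref <- reference_network()
  n_seg <- nrow(ref$segments)
  lapply(seq_len(count), function(i) {
    net <- ref
    if (perturbation > 0) {
      fac <- stats::runif(n_seg, 1 - perturbation, 1 + perturbation)
      net$segments$diameter <- net$segments$diameter * fac
    }
    if (remove_prob > 0 && stats::runif(1) < remove_prob) {
      victim <- sample(c("ACoA", "PCoAL", "PCoAR"), 1)
      net <- occlude(net, victim)
    }
    net
  })
}
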