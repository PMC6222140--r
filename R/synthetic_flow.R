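#' Generate a synthetic flow-cytometry event table
#'
#' Emulates dual-excitation acquisition of a cell suspension in ratio
#' mode: each event carries a 405-excited intensity, a 488-excited
#' intensity, and a third marker channel (Annexin-V- or TMRM-like).
#' Events are drawn from a mixture of lognormal populations; the generating
#' population id is retained as ground truth.
#'
#' @param n number of events (> 0).
#' @param populations a list; each element a list/vector with elements
#'   \code{fraction}, \code{mean405}, \code{mean488}, \code{mean_marker},
#'   \code{sd} (lognormal sdlog applied to all three channels).
#'   Fractions must sum to 1 (tolerance 1e-9).
#' @param seed integer seed.
#' @return A \code{data.frame} with columns \code{event_id}, \code{i405},
#'   \code{i488}, \code{marker}, \code{population}.
#' @export
generate_flow_events <- function(n, populations, seed = 1L) {
  stopifnot(n > 0, is.list(populations), length(populations) >= 1)
  fr <- vapply(populations, function(p) as.numeric(p[["fraction"]]), numeric(1))
  if (abs(sum(fr) - 1) > 1e-9)
    stop(sprintf("population fractions must sum to 1 (got %.12g)", sum(fr)))
  with_seed(seed, {
    pop <- sample.int(length(populations), n, replace = TRUE, prob = fr)
    draw <- function(field) {
      mu <- vapply(populations, function(p) as.numeric(p[[field]]), numeric(1))
      sdl <- vapply(populations, function(p) as.numeric(p[["sd"]]), numeric(1))
      stats::rlnorm(n, log(mu[pop]), sdl[pop])
    }
    data.frame(event_id = seq_len(n),
               i405 = draw("mean405"), i488 = draw("mean488"),
               marker = draw("mean_marker"), population = pop)
  })
}
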