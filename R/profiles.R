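#' Sample profiles for the acquisition simulator
#'
#' A sample profile bundles the statistical parameters of one simulated
#' acquisition experiment: how strongly recognition is biased to AAG PAMs
#' and to the displaced strand, how often a correctly recognised protospacer
#' is emitted as a derived (shifted or inverted) spacer, the hotspot
#' dispersion of per-protospacer usage, the per-base sequencing error rate
#' and the sampling seed.
#'
#' Packaged profiles (`spaceracq_profile("kd263")` etc.) describe primed
#' acquisition in cells expressing unit-sized crRNA with progressively
#' compromised Cas6e (`kd263`, `kd390`, `h20a`, `dcas6e`) plus a naive,
#' non-primed control (`naive`). Primed profiles share
#' `p_aag_recognition = 0.98` and differ in strand bias and derived-spacer
#' fraction; the naive profile has no PAM or strand bias.
#'
#' @param name Sample name.
#' @param mode `"primed"` or `"naive"`.
#' @param n_events Number of acquisition events to simulate.
#' @param p_aag_recognition Probability that a recognition event targets an
#'   AAG-PAM protospacer (primed default 0.98; naive 0.5).
#' @param p_derived Probability that an AAG recognition is emitted as a
#'   derived spacer (shifted or inverted) rather than the exact protospacer.
#' @param p_invert_given_derived Probability that a derived emission is
#'   inverted (else shifted).
#' @param shift_window Maximum absolute shift `k` for shifted emissions
#'   (`k` uniform over +/-1..+/-shift_window).
#' @param strand_bias Probability that an event originates from the
#'   displaced (priming-protospacer-bearing) strand.
#' @param hotspot_dispersion Log-sd of the log-normal per-protospacer usage
#'   weights.
#' @param error_rate Per-base substitution probability applied to rendered
#'   reads.
#' @param seed Integer sampling seed.
#' @return An object of class `sample_profile` (a validated named list).
#' @export
sample_profile <- function(name = "sample",
                           mode = c("primed", "naive"),
                           n_events = 20000L,
                           p_aag_recognition = if (mode == "primed") 0.98 else 0.50,
                           p_derived = 0.0398,
                           p_invert_given_derived = 0.5,
                           shift_window = 5L,
                           strand_bias = if (mode == "primed") 0.90 else 0.50,
                           hotspot_dispersion = 1.0,
                           error_rate = 0,
                           seed = 1L) {
  mode <- match.arg(mode)
  p <- list(
    name = name, mode = mode, n_events = as.integer(n_events),
    p_aag_recognition = p_aag_recognition, p_derived = p_derived,
    p_invert_given_derived = p_invert_given_derived,
    shift_window = as.integer(shift_window), strand_bias = strand_bias,
    hotspot_dispersion = hotspot_dispersion, error_rate = error_rate,
    seed = as.integer(seed)
  )
  probs <- c(
    "p_aag_recognition", "p_derived", "p_invert_given_derived",
    "strand_bias", "error_rate"
  )
  for (f in probs) {
    if (p[[f]] < 0 || p[[f]] > 1) abort(paste0(f, " must lie in [0, 1]"))
  }
  if (p$n_events <= 0L) abort("n_events must be positive")
  if (p$shift_window < 1L) abort("shift_window must be >= 1")
  if (p$hotspot_dispersion < 0) abort("hotspot_dispersion must be >= 0")
  structure(p, class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat("<sample_profile> ", x$name, " (", x$mode, ")\n", sep = "")
  cat(
    "  n_events=", x$n_events,
    " p_aag=", x$p_aag_recognition,
    " p_derived=", x$p_derived,
    " strand_bias=", x$strand_bias,
    " error_rate=", x$error_rate,
    " seed=", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Load a sample profile from a YAML file
#'
#' @param path Path to a YAML file whose keys are the fields of
#'   [sample_profile()].
#' @return A `sample_profile`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) abort(paste0("profile file not found: ", path))
  y <- yaml::read_yaml(path)
  do.call(sample_profile, y)
}

#' Packaged sample profiles
#'
#' @param name One of `"kd263"`, `"kd390"`, `"h20a"`, `"dcas6e"`, `"naive"`,
#'   or `NULL` to list the available names.
#' @return A `sample_profile`, or a character vector of names.
#' @export
spaceracq_profile <- function(name = NULL) {
  dir <- system.file("extdata", "profiles", package = "spaceracq")
  avail <- sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
  if (is.null(name)) return(avail)
  if (!name %in% avail) {
    abort(paste0("unknown profile '", name, "'; available: ", paste(avail, collapse = ", ")))
  }
  read_profile(file.path(dir, paste0(name, ".yaml")))
}
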