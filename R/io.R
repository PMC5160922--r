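#' Write a nutrient trace to a tab-separated file
#'
#' Traces are stored with nutrient *names*, never indices: columns `t`,
#' `nutrient` and, when present, `switch_state`, with a header line.
#' Round-trips losslessly through [read_trace()].
#'
#' @param trace A `nutrient_trace` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace), all(c("t", "nutrient") %in% names(trace)))
  df <- as.data.frame(trace)
  df$nutrient <- as.character(df$nutrient)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a nutrient trace from a tab-separated file
#'
#' @param path File path (header `t`, `nutrient`, optional `switch_state`).
#' @param alphabet Optional [nutrient_alphabet()]; if given, nutrient names
#'   outside it are rejected with the offending line number. Otherwise the
#'   alphabet is taken from the file in order of first appearance (Glu/Gal/Mal
#'   ordered canonically when applicable).
#' @return A `nutrient_trace` tibble.
#' @export
read_trace <- function(path, alphabet = NULL) {
  if (!file.exists(path)) abort(sprintf("Trace file not found: %s", path))
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e) abort(sprintf("Empty trace file: %s", path))
  )
  if (nrow(df) == 0) abort(sprintf("Empty trace file: %s", path))
  if (!all(c("t", "nutrient") %in% names(df))) {
    abort(sprintf("Trace file %s must have `t` and `nutrient` columns.", path))
  }
  if (is.null(alphabet)) {
    seen <- unique(df$nutrient)
    canon <- c("Glu", "Gal", "Mal")
    labels <- if (all(seen %in% canon)) canon[canon %in% seen] else seen
    if (length(labels) < 2) labels <- union(labels, setdiff(canon, labels))[1:2]
    alphabet <- nutrient_alphabet(labels)
  }
  bad <- which(!(df$nutrient %in% unclass(alphabet)))
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown nutrient '%s' at line %d of %s (alphabet: %s).",
      df$nutrient[bad[1]], bad[1] + 1L, path,
      paste(unclass(alphabet), collapse = ", ")))
  }
  sw <- if ("switch_state" %in% names(df)) as.integer(df$switch_state) else NULL
  new_nutrient_trace(df$t, match(df$nutrient, unclass(alphabet)), alphabet,
                     switch_state = sw)
}

#' Write an environment specification to YAML
#'
#' @param spec A `markov_env_spec` or `meta_env_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_env_spec <- function(spec, path) {
  x <- if (inherits(spec, "markov_env_spec")) {
    list(alphabet = unclass(spec$alphabet),
         transition_matrix = unname(apply(spec$transition_matrix, 1,
                                          as.numeric, simplify = FALSE)),
         initial = unclass(spec$alphabet)[spec$initial])
  } else if (inherits(spec, "meta_env_spec")) {
    list(alphabet = unclass(spec$alphabet),
         switch_matrix = unname(apply(spec$switch_matrix, 1, as.numeric,
                                      simplify = FALSE)),
         state_matrices = lapply(spec$state_matrices, function(m) {
           unname(apply(m, 1, as.numeric, simplify = FALSE))
         }),
         initial_switch = spec$initial_switch,
         initial_nutrient = unclass(spec$alphabet)[spec$initial_nutrient])
  } else {
    abort("`spec` must be a markov_env_spec or meta_env_spec.")
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read an environment specification from YAML
#'
#' The spec kind is detected from its keys: `transition_matrix` for Markov
#' environments, `switch_matrix` plus `state_matrices` for meta-changing
#' environments.
#'
#' @param path YAML file path.
#' @return A `markov_env_spec` or `meta_env_spec`.
#' @export
read_env_spec <- function(path) {
  if (!file.exists(path)) abort(sprintf("Spec file not found: %s", path))
  x <- yaml::read_yaml(path)
  if (is.null(x$alphabet)) {
    abort(sprintf("Spec file %s is missing the `alphabet` field.", path))
  }
  ab <- nutrient_alphabet(x$alphabet)
  to_matrix <- function(rows, what) {
    m <- tryCatch(do.call(rbind, lapply(rows, as.numeric)),
                  error = function(e) NULL)
    if (is.null(m)) abort(sprintf("Malformed `%s` in %s.", what, path))
    m
  }
  if (!is.null(x$transition_matrix)) {
    markov_env_spec(to_matrix(x$transition_matrix, "transition_matrix"), ab,
                    x$initial %||% 1L)
  } else if (!is.null(x$switch_matrix) && !is.null(x$state_matrices)) {
    meta_env_spec(to_matrix(x$switch_matrix, "switch_matrix"),
                  lapply(x$state_matrices, to_matrix, what = "state_matrices"),
                  ab,
                  initial_switch = x$initial_switch %||% 1L,
                  initial_nutrient = x$initial_nutrient %||% 1L)
  } else {
    abort(sprintf(
      "Spec file %s needs `transition_matrix` or `switch_matrix` + `state_matrices`.",
      path))
  }
}

#' Write / read an inference model specification (YAML)
#'
#' @param spec A [model_spec()].
#' @param path File path.
#' @return `path` (write) or a `model_spec` (read).
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  yaml::write_yaml(list(
    K = spec$K, J = spec$J,
    alpha_s1 = as.numeric(spec$alpha_s1),
    alpha_c0 = as.numeric(spec$alpha_c0),
    alpha_s_self = spec$alpha_s_self, alpha_s_other = spec$alpha_s_other,
    alpha_c = spec$alpha_c, labels = unclass(spec$alphabet)
  ), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) abort(sprintf("Spec file not found: %s", path))
  x <- yaml::read_yaml(path)
  model_spec(K = x$K %||% 2, J = x$J %||% 2,
             alpha_s1 = x$alpha_s1 %||% rep(1, x$K %||% 2),
             alpha_c0 = x$alpha_c0 %||% rep(1, x$J %||% 2),
             alpha_s_self = x$alpha_s_self %||% 2,
             alpha_s_other = x$alpha_s_other %||% 1,
             alpha_c = x$alpha_c %||% 1,
             labels = x$labels)
}

#' Write a particle-filter predictive sequence to TSV
#'
#' @param pf A `pf_filter` result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictive <- function(pf, path) {
  stopifnot(inherits(pf, "pf_filter"))
  utils::write.table(as.data.frame(pf), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
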