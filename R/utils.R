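#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that simulation functions are
#' deterministic for a fixed seed without disturbing the caller's stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_myelogate <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "myelogate_error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_myelogate(sprintf("`%s` must be a single finite number", name),
                   "validation_error")
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    stop_myelogate(sprintf("`%s` = %g is outside its allowed range", name, x),
                   "validation_error")
  invisible(x)
}

TISSUE_TYPES <- c("epilepsy", "meningioma", "low_grade", "grade_iv")
MICROGLIAL_MARKERS <- c("P2RY12", "TMEM119")
TAM_MARKERS <- c("CD14", "CD163")

#' Identify the microglial marker in a panel
#' @noRd
microglial_marker <- function(markers) {
  hit <- intersect(MICROGLIAL_MARKERS, markers)
  if (length(hit) != 1L)
    stop_myelogate(
      "marker panel must contain exactly one microglial marker (P2RY12 or TMEM119)",
      "validation_error")
  hit
}

highlow_marker <- function(markers) {
  hit <- intersect(TAM_MARKERS, markers)
  if (length(hit) > 1L)
    stop_myelogate("marker panel may contain at most one of CD14/CD163",
                   "validation_error")
  if (length(hit)) hit else NULL
}
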