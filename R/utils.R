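# Internal helpers shared across modules.

# 1 hartree in kcal/mol (CODATA-consistent constant used for table ingestion).
HARTREE_KCAL <- 627.509474

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded noise inside the package never perturbs user
#' simulations.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic small-integer hash of a character string, for deriving
# per-pair noise seeds from a master seed. Kept below 2^31 - 1.
str_seed <- function(master, s) {
  h <- as.numeric(master) %% 2147483647
  for (ch in utf8ToInt(s)) {
    h <- (h * 131 + ch) %% 2147483647  # doubles are exact below 2^53
  }
  as.integer(h)
}

# --- logging -----------------------------------------------------------------

.log_state <- new.env(parent = emptyenv())
.log_state$level <- "info"

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the package log level
#'
#' Structured log lines (timestamp, level, module, message) are written to
#' standard error by the command-line interface and long-running builders.
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  prev <- .log_state$level
  .log_state$level <- level
  invisible(prev)
}

log_msg <- function(level, module, msg) {
  if (.log_levels[[level]] < .log_levels[[.log_state$level]]) {
    return(invisible(NULL))
  }
  line <- sprintf("%s\t%s\t%s\t%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  toupper(level), module, msg)
  cat(line, "\n", sep = "", file = stderr())
  invisible(NULL)
}
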