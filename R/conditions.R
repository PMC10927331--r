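# Structured error conditions.  Every user-facing error carries a class so
# callers (and the CLI) can map failures to exit codes without string
# matching:
#   slimscan_input_error / _schema_error / _validation_error /
#   _compile_error / _io_error          -> bad input        (CLI exit 2)
#   slimscan_setup_error                -> cache missing    (CLI exit 3)
#   slimscan_resolution_error           -> unknown accession(CLI exit 4)
#   slimscan_contract_error             -> internal misuse

stop_slim <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "slimscan_error", "error")))
}

stop_input      <- function(msg) stop_slim(msg, "slimscan_input_error")
stop_schema     <- function(msg) stop_slim(msg, c("slimscan_schema_error", "slimscan_input_error"))
stop_validation <- function(msg) stop_slim(msg, c("slimscan_validation_error", "slimscan_input_error"))
stop_compile    <- function(msg) stop_slim(msg, c("slimscan_compile_error", "slimscan_input_error"))
stop_io         <- function(msg) stop_slim(msg, c("slimscan_io_error", "slimscan_input_error"))
stop_setup      <- function(msg) stop_slim(msg, "slimscan_setup_error")
stop_resolution <- function(msg) stop_slim(msg, "slimscan_resolution_error")
stop_contract   <- function(msg) stop_slim(msg, "slimscan_contract_error")

# Evaluate an expression with a temporary RNG state derived from `seed`,
# restoring the caller's RNG afterwards so library calls never perturb a
# user's random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
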