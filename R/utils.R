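#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif setNames
#' @importFrom utils head modifyList read.csv write.csv
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

hds_error <- function(msg, class) {
  stop(structure(
    class = c(class, "hds_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

config_error     <- function(msg) hds_error(msg, "hds_config_error")
validation_error <- function(msg) hds_error(msg, "hds_validation_error")
key_error        <- function(msg) hds_error(msg, "hds_key_error")
not_found_error  <- function(msg) hds_error(msg, "hds_not_found_error")
conflict_error   <- function(msg) hds_error(msg, "hds_conflict_error")
incompatibility_error <- function(msg) hds_error(msg, "hds_incompatibility_error")

# Evaluate `expr` under a deterministic RNG state derived from `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    config_error("seed must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# First 6 bytes of a raw digest as a double (48 bits, exact in a double).
raw_to_num <- function(r) {
  sum(as.numeric(r[1:6]) * 256^(5:0))
}

sha256_hex <- function(x) {
  # paste0 strips the openssl 'hash' class from the hex string
  paste0(as.character(openssl::sha256(charToRaw(x))))
}

# Canonical JSON-ish fingerprint of a list (order-stable).
fingerprint <- function(x) {
  ser <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, sort = TRUE)
  substr(sha256_hex(as.character(ser)), 1, 16)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)

now_stamp <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")
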