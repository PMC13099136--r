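#' Derive a reproducible child seed from a master seed and a tag
#'
#' Stages of the pipeline (and per-session, per-trial-type draws) use seeds
#' derived by stable string hashing so that each stage is reproducible in
#' isolation and independent of the order in which other stages run.
#'
#' @param master Integer master seed.
#' @param ... Character/numeric tag components identifying the consumer.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  tag <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% 2147483629
  as.integer((as.numeric(master) %% 2147483629 + h) %% 2147483629)
}

# Evaluate an expression with a local RNG state (does not disturb the caller's).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Internal condition helpers: validation errors carry the offending trial/unit.
sg_stop <- function(..., class = "stategen_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

sg_validation_error <- function(...) {
  sg_stop(..., class = c("stategen_validation_error", "stategen_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
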