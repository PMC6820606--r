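#' Geometric mean
#'
#' @param x positive numeric vector.
#' @param na.rm drop missing values first.
#' @return Geometric mean of `x`.
#' @export
geo_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

## trapezoidal rule on an ordered grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

## evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

## draw n samples from Normal(mean, sd) truncated to (lo, hi) by inverse CDF
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

## analytic mean of a truncated normal (used by tests and documentation)
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

#' Write a run manifest
#'
#' Records the command, configuration hash, seeds and file paths of an
#' analysis stage so that deterministic stages can be reproduced
#' bit-identically.
#'
#' @param command name of the stage that was run.
#' @param seed integer seed(s) used by the stage.
#' @param inputs,outputs character vectors of file paths.
#' @param config optional list; hashed (serialized md5) into the manifest.
#' @param path file to write the manifest JSON to.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(command, seed = NULL, inputs = character(),
                           outputs = character(), config = NULL, path) {
  manifest <- list(
    command = command,
    config_hash = if (is.null(config)) NA_character_ else
      digest_list(config),
    seed = seed,
    inputs = inputs,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("atezodose")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(manifest)
}

## stable content hash of a list without extra dependencies
digest_list <- function(x) {
  con <- textConnection(NULL, "w", local = TRUE)
  dput(x, file = con)
  txt <- paste(textConnectionValue(con), collapse = "\n")
  close(con)
  ## md5 of the deparsed representation
  tf <- tempfile()
  writeLines(txt, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}
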