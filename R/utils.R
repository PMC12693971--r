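`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG state and restore the caller's state after.
# Pins the RNG kind so that seeded output is reproducible across sessions.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

site_key <- function(chrom, pos) paste0(chrom, ":", pos)

assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  }
  invisible(df)
}

SUPERCLUSTERS <- c("EUR", "AFR", "SAS", "EAS", "Uncategorized")

NONRESPONSE_CODES <- c("Do not know", "Do not want to answer",
                       "None of the above")
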