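# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# stable short hash of an R object (for provenance headers)
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(x, file = tf)
  unname(substr(tools::md5sum(tf), 1L, 12L))
}

#' Write a data frame as TSV with a provenance header
#'
#' All pipeline outputs carry a header comment recording the package
#' version, the seed and a hash of the generating configuration, so that
#' two runs with identical config and seed are byte-identical.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param seed Seed used by the generating command (or `NA`).
#' @param config Configuration object to hash into the header.
#' @export
write_tsv_report <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nsvatlas %s; seed=%s; config=%s",
                     as.character(utils::packageVersion("nsvatlas")),
                     as.character(seed),
                     if (is.null(config)) "-" else config_hash(config)), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    rows <- do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) {
        format(col, digits = 10, trim = TRUE, scientific = FALSE)
      } else as.character(col)
    }), sep = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}
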