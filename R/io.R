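#' Table schemas for the pipeline interchange files
#'
#' Declarative column schemas used by [read_table()] and [write_table()].
#' Each schema names its required columns with types, the key columns
#' whose combinations must be unique, and the columns required to be
#' finite.
#'
#' @param name One of `"spectra"`, `"params"`, `"suvr"`, `"bands"`.
#' @return A list with `name`, `columns` (named character of types),
#'   `key`, `finite`.
#' @export
table_schema <- function(name = c("spectra", "params", "suvr", "bands")) {
  name <- match.arg(name)
  switch(name,
    spectra = list(name = name,
                   columns = c(subject_id = "character", roi = "character",
                               frequency_hz = "numeric", psd_db = "numeric"),
                   key = c("subject_id", "roi", "frequency_hz"),
                   finite = c("frequency_hz", "psd_db")),
    params = list(name = name,
                  columns = c(subject_id = "character", roi = "character",
                              tau_e_ms = "numeric", tau_i_ms = "numeric",
                              g_ee = "numeric", g_ii = "numeric"),
                  key = c("subject_id", "roi"),
                  finite = c("tau_e_ms", "tau_i_ms", "g_ee", "g_ii")),
    suvr = list(name = name,
                columns = c(subject_id = "character", roi = "character",
                            tau_suvr = "numeric", ab_suvr = "numeric"),
                key = c("subject_id", "roi"),
                finite = c("tau_suvr", "ab_suvr")),
    bands = list(name = name,
                 columns = c(subject_id = "character", roi = "character",
                             band = "character", power_db = "numeric"),
                 key = c("subject_id", "roi", "band"),
                 finite = c("power_db")))
}

.validate_table <- function(df, schema) {
  miss <- setdiff(names(schema$columns), names(df))
  if (length(miss) > 0)
    stop(sprintf("%s table missing column(s): %s", schema$name,
                 paste(miss, collapse = ", ")), call. = FALSE)
  for (col in names(schema$columns)) {
    if (schema$columns[[col]] == "numeric") {
      if (!is.numeric(df[[col]]))
        stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
    } else {
      df[[col]] <- as.character(df[[col]])
    }
  }
  keys <- do.call(paste, c(df[schema$key], sep = "\r"))
  if (anyDuplicated(keys)) {
    dup <- df[duplicated(keys), schema$key, drop = FALSE][1, ]
    stop(sprintf("duplicate key in %s table (first offender: %s)",
                 schema$name, paste(unlist(dup), collapse = " / ")),
         call. = FALSE)
  }
  for (col in schema$finite)
    if (any(!is.finite(df[[col]])))
      stop(sprintf("non-finite values in column '%s'", col), call. = FALSE)
  df
}

#' Read or write a validated pipeline table
#'
#' Tables are tidy CSV with an optional metadata header of `# key: value`
#' comment lines (seed, config hash, package version). `read_table`
#' validates against the schema (presence and type of declared columns,
#' uniqueness of key combinations, finiteness) and preserves any extra
#' columns; `write_table` validates before writing. A write-then-read
#' round trip is the identity on the declared columns.
#'
#' @param path File path.
#' @param schema A [table_schema()] or schema name.
#' @param df Data.frame to write.
#' @param meta Named list written as `# key: value` header lines.
#' @return `read_table`: the validated data.frame, with any metadata
#'   header in `attr(., "meta")`. `write_table`: the path, invisibly.
#' @export
read_table <- function(path, schema) {
  if (is.character(schema)) schema <- table_schema(schema)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  head_lines <- character(0)
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0 || !startsWith(ln, "#")) break
    head_lines <- c(head_lines, ln)
  }
  close(con); on.exit()
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df <- .validate_table(df, schema)
  meta <- list()
  for (ln in head_lines) {
    kv <- sub("^#\\s*", "", ln)
    i <- regexpr(":", kv, fixed = TRUE)
    if (i > 0) meta[[trimws(substr(kv, 1, i - 1))]] <-
        trimws(substr(kv, i + 1, nchar(kv)))
  }
  attr(df, "meta") <- meta
  df
}

#' @rdname read_table
#' @export
write_table <- function(df, path, schema, meta = list()) {
  if (is.character(schema)) schema <- table_schema(schema)
  df <- .validate_table(df, schema)
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(table = schema$name,
                 package = paste0("nmmspectra ",
                                  as.character(utils::packageVersion("nmmspectra")))),
            meta)
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, as.character(meta[[k]])), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Convert between spectrum objects and the tidy spectra table
#'
#' @param spectra List of [regional_spectrum()] objects.
#' @param df A spectra-schema data.frame.
#' @return `spectra_to_table`: tidy data.frame (subject_id, roi,
#'   frequency_hz, psd_db). `table_to_spectra`: list of
#'   [regional_spectrum()], one per subject-by-ROI.
#' @export
spectra_to_table <- function(spectra) {
  out <- do.call(rbind, lapply(spectra, function(sp) {
    data.frame(subject_id = sp$subject_id, roi = sp$roi,
               frequency_hz = sp$grid, psd_db = sp$psd_db,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @rdname spectra_to_table
#' @export
table_to_spectra <- function(df) {
  df <- .validate_table(df, table_schema("spectra"))
  keys <- unique(df[, c("subject_id", "roi")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- df$subject_id == keys$subject_id[i] & df$roi == keys$roi[i]
    sub <- df[sel, ]
    sub <- sub[order(sub$frequency_hz), ]
    regional_spectrum(sub$frequency_hz, sub$psd_db,
                      subject_id = keys$subject_id[i], roi = keys$roi[i])
  })
}

#' Read/write a parameter set as JSON or YAML
#'
#' @param params An [nmm_params()] object.
#' @param path Destination/source path ending in `.json`, `.yaml`, or
#'   `.yml`.
#' @return `write_params`: the path, invisibly; `read_params`: an
#'   [nmm_params()].
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "nmm_params"))
  x <- as.list(params)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  as_nmm_params(x)
}
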