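# Internal serialization helpers.

# Write a data frame with numeric columns at 17 significant digits so that
# write -> read round trips are bit-exact.
.writeTable <- function(df, path, sep = "\t") {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]]))
      df[[j]] <- vapply(df[[j]], function(v)
        if (is.na(v)) "NA" else sprintf("%.17g", v), character(1))
  }
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

# Canonical JSON form of a CohortConfig (used for manifests and hashing).
.configAsList <- function(config) {
  nms <- slotNames(config)
  out <- lapply(nms, function(nm) slot(config, nm))
  names(out) <- nms
  out
}

# Deterministic md5 of the canonical JSON serialization.
.configHash <- function(config) {
  json <- jsonlite::toJSON(.configAsList(config), auto_unbox = TRUE,
                           digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}
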