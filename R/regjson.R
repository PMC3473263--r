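# RegJSON: the package's JSON dialect for regulatory models.
#
# Top-level keys: format_version, model_id, and the eight entity arrays.
# The writer is canonical: arrays sorted by id, keys in a fixed order,
# absent optional fields omitted, so equal models serialise byte-equal.

REGJSON_VERSION <- "1.0"

REGJSON_KEYS <- c("format_version", "model_id", MODEL_TABLES)

# fields serialised per table, in order; list-typed ones written as arrays
regjson_field_order <- function() {
  spec <- model_table_spec()
  lapply(spec, names)
}

#' Read a regulatory model from a RegJSON file
#'
#' Parses the JSON document, rejects unknown top-level keys, assembles a
#' [regulatory_model()] and runs [validate_model()]; any validation error
#' aborts with a report naming the offending entities.
#'
#' @param path Path to a RegJSON file.
#' @return A validated [regulatory_model()].
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  unknown <- setdiff(names(doc), REGJSON_KEYS)
  if (length(unknown)) {
    stop("unknown top-level RegJSON key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  spec <- model_table_spec()
  tabs <- lapply(MODEL_TABLES, function(tbl) {
    records_to_tibble(doc[[tbl]], spec[[tbl]])
  })
  names(tabs) <- MODEL_TABLES
  model <- regulatory_model(
    genes = tabs$genes,
    transcription_units = tabs$transcription_units,
    promoters = tabs$promoters,
    terminators = tabs$terminators,
    products = tabs$products,
    compounds = tabs$compounds,
    reactions = tabs$reactions,
    regulations = tabs$regulations,
    id = if (!is.null(doc$model_id)) doc$model_id else "model"
  )
  report <- validate_model(model)
  if (nrow(report) > 0) {
    msg <- paste0(report$entity_id, ": ", report$rule, " (", report$detail, ")")
    stop("model failed validation (", nrow(report), " error",
         if (nrow(report) > 1) "s" else "", "):\n  ",
         paste(utils::head(msg, 20), collapse = "\n  "),
         if (nrow(report) > 20) "\n  ..." else "",
         call. = FALSE)
  }
  model
}

records_to_tibble <- function(records, spec) {
  if (is.null(records) || length(records) == 0) return(NULL)
  cols <- lapply(names(spec), function(col) {
    type <- spec[[col]]
    vals <- lapply(records, function(r) {
      v <- r[[col]]
      if (col == "binding_site_position" && is.null(v))
        v <- r[["binding_site"]][["position"]]
      if (col == "binding_site_description" && is.null(v))
        v <- r[["binding_site"]][["description"]]
      v
    })
    switch(type,
      chr = vapply(vals, function(v)
        if (is.null(v)) NA_character_ else as.character(v), character(1)),
      int = vapply(vals, function(v)
        if (is.null(v)) NA_integer_ else as.integer(v), integer(1)),
      lgl = vapply(vals, function(v)
        if (is.null(v)) NA else as.logical(v), logical(1)),
      list = lapply(vals, function(v)
        if (is.null(v)) character(0) else
          as.character(unlist(v, use.names = FALSE)))
    )
  })
  names(cols) <- names(spec)
  tibble::as_tibble(cols)
}

#' Write a regulatory model to a RegJSON file
#'
#' Canonical serialisation: entity arrays are sorted by id, object keys
#' appear in a fixed order, and absent optional fields are omitted, so two
#' structurally equal models produce byte-identical files and
#' `write_model()` is idempotent across read/write round trips.
#'
#' @param model A [regulatory_model()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "regulatory_model"))
  spec <- model_table_spec()
  doc <- list(
    format_version = jsonlite::unbox(REGJSON_VERSION),
    model_id = jsonlite::unbox(model$id)
  )
  for (tbl in MODEL_TABLES) {
    df <- model[[tbl]]
    df <- df[order(df$id), , drop = FALSE]
    recs <- lapply(seq_len(nrow(df)), function(i) {
      row_to_record(df[i, ], spec[[tbl]])
    })
    doc[[tbl]] <- recs
  }
  json <- jsonlite::toJSON(doc, auto_unbox = FALSE, pretty = 2, digits = NA,
                           null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

row_to_record <- function(row, spec) {
  rec <- list()
  bs_pos <- NA_integer_
  bs_desc <- NA_character_
  for (col in names(spec)) {
    type <- spec[[col]]
    v <- row[[col]]
    if (type == "list") v <- v[[1]]
    if (col == "binding_site_position") { bs_pos <- v; next }
    if (col == "binding_site_description") { bs_desc <- v; next }
    if (type == "list") {
      if (length(v) > 0) rec[[col]] <- as.character(v)
    } else if (!is.na(v)) {
      rec[[col]] <- jsonlite::unbox(v)
    }
  }
  if (!is.na(bs_pos) || !is.na(bs_desc)) {
    bs <- list()
    if (!is.na(bs_pos)) bs$position <- jsonlite::unbox(as.integer(bs_pos))
    if (!is.na(bs_desc)) bs$description <- jsonlite::unbox(bs_desc)
    rec$binding_site <- bs
  }
  rec
}
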