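# Tabular I/O: spot tables (a GPR-inspired tab-delimited subset), Ct
# tables, expression matrices and annotation tables. All files are UTF-8,
# tab-delimited, Unix newlines; numeric fields are written with 9
# significant digits so round trips preserve intensities well past the 6
# significant digits the scanner reports.

SPOT_COLUMNS <- c("Block", "Row", "Column", "ProbeID", "GeneID", "SpotType",
                  "F_Median")
SPOT_TYPES <- c("gene", "blank", "control")
ND_TOKEN <- "ND"

fmt_num <- function(x) {
  out <- sprintf("%.9g", x)
  out[is.na(x)] <- "NA"
  out
}

# write.table wrapper with fixed number formatting so identical inputs give
# byte-identical files
write_tsv_deterministic <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out)) {
    lines <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

read_tsv_plain <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Construct an array scan (one hybridization's spot records)
#'
#' @param records `data.frame` with columns `block`, `row`, `col` (1-based
#'   grid coordinates), `probe_id`, `gene_id` (empty string for blanks),
#'   `spot_type` (`gene`, `blank` or `control`) and `foreground` (median
#'   foreground intensity, `>= 0`).
#' @param sample sample label.
#' @param method one of `"non_amp"`, `"amp1"`, `"amp2"`.
#' @param replicate replicate index (`>= 1`).
#' @param platform_size expected number of gene spots; defaults to the
#'   number present.
#' @return an object of class `array_scan`.
#' @export
array_scan <- function(records, sample, method, replicate,
                       platform_size = NULL) {
  required <- c("block", "row", "col", "probe_id", "gene_id", "spot_type",
                "foreground")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    abort_schema(sprintf("spot records missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  match_method(method)
  if (!is.numeric(replicate) || length(replicate) != 1L || replicate < 1) {
    abort_input("`replicate` must be a positive index")
  }
  if (!all(records$spot_type %in% SPOT_TYPES)) {
    abort_integrity(sprintf("spot_type must be one of: %s",
                            paste(SPOT_TYPES, collapse = ", ")))
  }
  if (anyDuplicated(records[c("block", "row", "col")])) {
    abort_integrity("duplicate (block, row, col) spot coordinates")
  }
  if (any(!is.finite(records$foreground)) || any(records$foreground < 0)) {
    abort_integrity("foreground intensities must be finite and >= 0")
  }
  n_blank <- sum(records$spot_type == "blank")
  if (n_blank < 1L) {
    abort_integrity("scan has no blank spots; background is undefined")
  }
  gene_ids <- records$gene_id[records$spot_type == "gene"]
  if (any(gene_ids == "")) abort_integrity("gene spots must carry a gene_id")
  if (anyDuplicated(gene_ids)) {
    abort_integrity("duplicate gene_id among gene spots (one spot per gene expected)")
  }
  n_gene <- length(gene_ids)
  structure(list(
    records = records,
    sample = as.character(sample),
    method = method,
    replicate = as.integer(replicate),
    platform_size = as.integer(platform_size %||% n_gene)
  ), class = "array_scan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.array_scan <- function(x, ...) {
  tab <- table(factor(x$records$spot_type, levels = SPOT_TYPES))
  cat(sprintf("Array scan: sample %s, method %s, replicate %d\n",
              x$sample, x$method, x$replicate))
  cat(sprintf("  %d gene, %d blank, %d control spots\n",
              tab[["gene"]], tab[["blank"]], tab[["control"]]))
  invisible(x)
}

# spot subsets used throughout the quantification module
blank_foregrounds <- function(scan) {
  scan$records$foreground[scan$records$spot_type == "blank"]
}
gene_spots <- function(scan) {
  scan$records[scan$records$spot_type == "gene", , drop = FALSE]
}

#' Write / read a spot table
#'
#' The on-disk dialect is a tab-delimited GPR-inspired subset: `#`-prefixed
#' `key=value` metadata lines (sample, method, replicate, platform_size),
#' then a header row `Block Row Column ProbeID GeneID SpotType F_Median`
#' and one row per spot. Writing the same scan twice yields byte-identical
#' files.
#'
#' @param scan an [array_scan()].
#' @param path file path.
#' @return `write_spot_table()` returns `path` invisibly;
#'   `read_spot_table()` returns an [array_scan()].
#' @export
write_spot_table <- function(scan, path) {
  if (!inherits(scan, "array_scan")) abort_input("`scan` must be an array_scan")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sample=%s", scan$sample),
    sprintf("# method=%s", scan$method),
    sprintf("# replicate=%d", scan$replicate),
    sprintf("# platform_size=%d", scan$platform_size),
    paste(SPOT_COLUMNS, collapse = "\t")
  ), con, sep = "\n")
  r <- scan$records
  writeLines(paste(r$block, r$row, r$col, r$probe_id, r$gene_id, r$spot_type,
                   fmt_num(r$foreground), sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- startsWith(lines, "#")
  if (all(is_meta)) abort_schema("spot table has no header row")
  meta_lines <- lines[is_meta & seq_along(lines) < which(!is_meta)[1]]
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- lines[!is_meta]
  if (length(body) < 1L) abort_schema("spot table has no header row")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(SPOT_COLUMNS, header)
  if (length(missing)) {
    abort_schema(sprintf("spot table missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  data_lines <- body[-1]
  if (!length(data_lines)) abort_schema("spot table has no data rows")
  cells <- strsplit(data_lines, "\t", fixed = TRUE)
  ncol_bad <- which(lengths(cells) != length(header))
  if (length(ncol_bad)) {
    abort_schema(sprintf("row %d has %d fields, expected %d",
                         ncol_bad[1], lengths(cells)[ncol_bad[1]], length(header)))
  }
  mat <- do.call(rbind, cells)
  colnames(mat) <- header
  parse_int <- function(colname) {
    raw <- mat[, colname]
    val <- suppressWarnings(as.integer(raw))
    bad <- which(is.na(val))
    if (length(bad)) {
      abort_schema(sprintf("malformed integer '%s' in column %s, row %d",
                           raw[bad[1]], colname, bad[1]))
    }
    val
  }
  raw_fg <- mat[, "F_Median"]
  fg <- suppressWarnings(as.numeric(raw_fg))
  bad <- which(is.na(fg))
  if (length(bad)) {
    abort_schema(sprintf("malformed numeric '%s' in column F_Median, row %d",
                         raw_fg[bad[1]], bad[1]))
  }
  if (any(fg < 0)) abort_integrity("negative foreground intensity in spot table")
  records <- data.frame(
    block = parse_int("Block"), row = parse_int("Row"), col = parse_int("Column"),
    probe_id = mat[, "ProbeID"], gene_id = mat[, "GeneID"],
    spot_type = mat[, "SpotType"], foreground = fg,
    stringsAsFactors = FALSE
  )
  array_scan(records,
             sample = meta$sample %||% "unknown",
             method = meta$method %||% abort_schema("missing '# method=' header"),
             replicate = as.integer(meta$replicate %||% 1L),
             platform_size = as.integer(meta$platform_size %||% sum(records$spot_type == "gene")))
}

#' Construct a qRT-PCR Ct table
#'
#' @param entries long `data.frame` with columns `gene_id`, `sample`, `ct`
#'   (mean threshold cycle over technical replicates; `NA` = not detected).
#' @param replicate_count technical replicates behind each mean (default 4).
#' @return an object of class `ct_table` (a `data.frame`).
#' @export
ct_table <- function(entries, replicate_count = 4L) {
  required <- c("gene_id", "sample", "ct")
  missing <- setdiff(required, names(entries))
  if (length(missing)) {
    abort_schema(sprintf("Ct table missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (nrow(entries) == 0L) abort_schema("Ct table has no entries")
  if (anyDuplicated(entries[c("gene_id", "sample")])) {
    abort_integrity("duplicate (gene_id, sample) in Ct table")
  }
  if (any(is.infinite(entries$ct), na.rm = TRUE)) {
    abort_integrity("Ct values must be finite or NA (not detected)")
  }
  entries <- entries[c("gene_id", "sample", "ct")]
  rownames(entries) <- NULL
  structure(entries, replicate_count = as.integer(replicate_count),
            class = c("ct_table", "data.frame"))
}

#' Write / read a Ct table
#'
#' TSV with columns `gene_id`, `sample`, `ct`; not-detected entries are
#' written as the literal token `ND`.
#'
#' @param ct a [ct_table()].
#' @param path file path.
#' @return `write_ct_table()` returns `path` invisibly; `read_ct_table()`
#'   returns a [ct_table()].
#' @export
write_ct_table <- function(ct, path) {
  if (!inherits(ct, "ct_table")) abort_input("`ct` must be a ct_table")
  out <- data.frame(gene_id = ct$gene_id, sample = ct$sample,
                    ct = ifelse(is.na(ct$ct), ND_TOKEN, fmt_num(ct$ct)),
                    replicate_count = attr(ct, "replicate_count"),
                    stringsAsFactors = FALSE)
  write_tsv_deterministic(out, path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  df <- read_tsv_plain(path)
  missing <- setdiff(c("gene_id", "sample", "ct"), names(df))
  if (length(missing)) {
    abort_schema(sprintf("Ct table missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  raw <- as.character(df$ct)
  ctv <- suppressWarnings(as.numeric(ifelse(raw == ND_TOKEN, NA, raw)))
  bad <- which(is.na(ctv) & raw != ND_TOKEN)
  if (length(bad)) {
    abort_schema(sprintf("malformed Ct value '%s' at row %d", raw[bad[1]], bad[1]))
  }
  rc <- if ("replicate_count" %in% names(df)) df$replicate_count[1] else 4L
  ct_table(data.frame(gene_id = as.character(df$gene_id),
                      sample = as.character(df$sample), ct = ctv,
                      stringsAsFactors = FALSE),
           replicate_count = rc)
}

#' Write / read an expression matrix
#'
#' Genes as rows; for each array a value column (normalized net intensity;
#' `NA` when undetected) paired with an `<array>.detected` boolean column.
#'
#' @param em a `data.frame` with a `gene_id` column plus paired
#'   value/`.detected` columns, as built by [build_expression_matrix()].
#' @param path file path.
#' @return `write_expression_matrix()` returns `path` invisibly;
#'   `read_expression_matrix()` returns the `data.frame`.
#' @export
write_expression_matrix <- function(em, path) {
  if (!is.data.frame(em) || !"gene_id" %in% names(em) || nrow(em) == 0L) {
    abort_schema("expression matrix must be a non-empty data.frame with a gene_id column")
  }
  write_tsv_deterministic(em, path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv_plain(path)
  if (!"gene_id" %in% names(df) || nrow(df) == 0L) {
    abort_schema("expression matrix must have a gene_id column and at least one row")
  }
  det_cols <- grep("\\.detected$", names(df), value = TRUE)
  for (cc in det_cols) df[[cc]] <- as.logical(df[[cc]])
  value_cols <- setdiff(names(df), c("gene_id", det_cols))
  if (!length(value_cols) || !setequal(paste0(value_cols, ".detected"), det_cols)) {
    abort_schema("each array value column needs a matching .detected column")
  }
  df
}

#' Write / read a gene annotation table
#'
#' The feature table of [generate_gene_features()] plus the study's panel
#' flags (`is_reference`, `panel`, `bias_susceptible`).
#'
#' @param annotation annotation `data.frame`.
#' @param path file path.
#' @return `write_annotation_table()` returns `path` invisibly;
#'   `read_annotation_table()` returns the `data.frame`.
#' @export
write_annotation_table <- function(annotation, path) {
  validate_features(annotation)
  write_tsv_deterministic(annotation, path)
}

#' @rdname write_annotation_table
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv_plain(path)
  validate_features(df)
  for (cc in intersect(c("is_reference", "panel", "bias_susceptible"), names(df))) {
    df[[cc]] <- as.logical(df[[cc]])
  }
  df
}
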