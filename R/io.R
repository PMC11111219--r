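#' Read a 10x-style count triplet (Matrix Market + features + barcodes)
#'
#' Reads a gene-by-cell UMI count matrix stored in the 10x Genomics triplet
#' layout: a Matrix Market coordinate file plus a features/genes table and a
#' barcodes table. Plain and gzipped files are auto-detected by magic bytes,
#' not by extension.
#'
#' @param path Either a directory containing `matrix.mtx`, `features.tsv` (or
#'   `genes.tsv`) and `barcodes.tsv` (optionally gzipped), or a character
#'   vector of length 3 giving the matrix, features and barcodes paths in that
#'   order.
#' @return A [`Matrix::dgCMatrix-class`] of non-negative integer counts with
#'   gene symbols as rownames and cell barcodes as colnames. Gene symbols are
#'   taken from column 2 of the features table when the 3-column 10x dialect
#'   is present, else column 1. Duplicate symbols are made unique by suffixing
#'   `.1`, `.2`, ... in file order (the number of renamed symbols is messaged).
#' @details Raw counts must be integral: a Matrix Market file with fractional
#'   values is rejected. Dimension mismatches between the Matrix Market header
#'   and the features/barcodes tables, and duplicate barcodes, are format
#'   errors naming the offending file.
#' @seealso [write_counts_10x()]
#' @export
read_counts_10x <- function(path) {
  paths <- locate_10x_triplet(path)
  con <- open_maybe_gz(paths$matrix)
  m <- tryCatch(Matrix::readMM(con),
                error = function(e) stop_format("malformed Matrix Market file '%s': %s",
                                                paths$matrix, conditionMessage(e)))
  close(con)
  if (is(m, "nsparseMatrix")) {
    m <- as(m, "dMatrix")
  }
  m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(m@x < 0) || any(m@x != round(m@x))) {
    stop_format("non-integer or negative count values in '%s': raw UMI counts must be non-negative integers",
                paths$matrix)
  }
  feats <- read_lines_maybe_gz(paths$features)
  barcodes <- read_lines_maybe_gz(paths$barcodes)
  if (length(feats) != nrow(m)) {
    stop_format("features file '%s' has %d rows but matrix header declares %d genes",
                paths$features, length(feats), nrow(m))
  }
  if (length(barcodes) != ncol(m)) {
    stop_format("barcodes file '%s' has %d rows but matrix header declares %d cells",
                paths$barcodes, length(barcodes), ncol(m))
  }
  if (anyDuplicated(barcodes)) {
    stop_format("duplicate cell barcodes in '%s' (e.g. '%s')",
                paths$barcodes, barcodes[duplicated(barcodes)][1])
  }
  genes <- parse_feature_symbols(feats)
  if (anyDuplicated(genes)) {
    ndup <- sum(duplicated(genes))
    genes <- dedup_symbols(genes)
    message(sprintf("made %d duplicate gene symbol(s) unique by suffixing .1, .2, ...", ndup))
  }
  dimnames(m) <- list(genes, barcodes)
  validate_counts(m)
  m
}

locate_10x_triplet <- function(path) {
  if (length(path) == 3L) {
    p <- list(matrix = path[[1]], features = path[[2]], barcodes = path[[3]])
  } else if (length(path) == 1L && dir.exists(path)) {
    pick <- function(cands) {
      for (f in cands) {
        full <- file.path(path, f)
        if (file.exists(full)) return(full)
      }
      stop_format("no %s file found in '%s'", cands[1], path)
    }
    p <- list(
      matrix   = pick(c("matrix.mtx", "matrix.mtx.gz")),
      features = pick(c("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz")),
      barcodes = pick(c("barcodes.tsv", "barcodes.tsv.gz"))
    )
  } else {
    stop_format("'path' must be an existing directory or a vector of 3 file paths")
  }
  for (f in p) if (!file.exists(f)) stop_format("file '%s' does not exist", f)
  p
}

read_lines_maybe_gz <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  readLines(con)
}

# 10x 3-column dialect (id, symbol, type) -> column 2; plain lists -> column 1.
parse_feature_symbols <- function(lines) {
  if (length(lines) == 0L) return(character(0))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  col <- if (all(ncols >= 2L)) 2L else 1L
  vapply(fields, `[[`, character(1), col)
}

dedup_symbols <- function(genes) {
  dup <- duplicated(genes)
  if (!any(dup)) return(genes)
  counts <- new.env(parent = emptyenv())
  out <- genes
  for (i in which(dup)) {
    g <- genes[i]
    k <- (get0(g, envir = counts) %||% 0L) + 1L
    assign(g, k, envir = counts)
    out[i] <- paste0(g, ".", k)
  }
  # suffixed names could themselves collide with existing symbols; recurse
  if (anyDuplicated(out)) out <- dedup_symbols(out)
  out
}

#' Validate a gene-by-cell count matrix
#'
#' Checks the count-matrix contract: a sparse numeric matrix with non-negative
#' integral entries, unique gene rownames and unique barcode colnames.
#'
#' @param m A matrix coercible to `dgCMatrix` with dimnames.
#' @return The validated `dgCMatrix`, invisibly.
#' @export
validate_counts <- function(m) {
  if (!is(m, "CsparseMatrix")) m <- as(as(m, "generalMatrix"), "CsparseMatrix")
  if ((nrow(m) > 0 && is.null(rownames(m))) || (ncol(m) > 0 && is.null(colnames(m)))) {
    stop_format("count matrix must carry gene rownames and barcode colnames")
  }
  if (anyDuplicated(rownames(m))) stop_format("duplicate gene symbols in count matrix")
  if (anyDuplicated(colnames(m))) stop_format("duplicate barcodes in count matrix")
  x <- m@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop_format("count matrix contains negative or non-integral values")
  }
  invisible(m)
}

#' Write a count matrix as a 10x-style triplet
#'
#' Emits `matrix.mtx` (Matrix Market, `coordinate integer general` dialect),
#' `features.tsv` (one symbol per line) and `barcodes.tsv` into `path`. The
#' triplet round-trips losslessly through [read_counts_10x()]: counts, gene
#' order and barcode order are preserved exactly.
#'
#' @param m Count matrix (genes x cells) with dimnames; validated first.
#' @param path Output directory, created if absent.
#' @param gzip Write gzipped files (`.gz` suffixes added).
#' @return The output directory, invisibly.
#' @export
write_counts_10x <- function(m, path, gzip = FALSE) {
  m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  validate_counts(m)
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  opener <- function(f) if (gzip) gzfile(f, open = "wb") else file(f, open = "wb")
  write_mm_integer(m, file.path(path, paste0("matrix.mtx", ext)), opener)
  con <- opener(file.path(path, paste0("features.tsv", ext)))
  writeLines(rownames(m) %||% character(0), con); close(con)
  con <- opener(file.path(path, paste0("barcodes.tsv", ext)))
  writeLines(colnames(m) %||% character(0), con); close(con)
  invisible(path)
}

# Matrix::writeMM picks symmetric/pattern dialects depending on content, so the
# integer coordinate writer is done by hand to keep the on-disk dialect fixed.
write_mm_integer <- function(m, file, opener) {
  t <- as(m, "TsparseMatrix")
  con <- opener(file)
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(t@x))), con)
  if (length(t@x)) {
    writeLines(sprintf("%d %d %d", t@i + 1L, t@j + 1L, as.integer(t@x)), con)
  }
  invisible(file)
}

#' Write a real-valued matrix (e.g. normalized expression) as Matrix Market
#'
#' Companion to [write_counts_10x()] for non-integer matrices: emits
#' `matrix.mtx` in the `coordinate real general` dialect plus `features.tsv`
#' and `barcodes.tsv`.
#'
#' @param m Real-valued sparse matrix with dimnames.
#' @param path Output directory, created if absent.
#' @return The output directory, invisibly.
#' @export
write_matrix_real <- function(m, path) {
  m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  t <- as(m, "TsparseMatrix")
  con <- file(file.path(path, "matrix.mtx"), open = "wb")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(t@x))), con)
  if (length(t@x)) {
    writeLines(sprintf("%d %d %.17g", t@i + 1L, t@j + 1L, t@x), con)
  }
  close(con)
  writeLines(rownames(m), file.path(path, "features.tsv"))
  writeLines(colnames(m), file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' Read a per-cell annotation table
#'
#' @param path TSV with a header; must contain a `barcode` column. Typical
#'   further columns: `sample`, `condition`, `cluster`.
#' @return A data.frame with one row per cell; barcodes are checked unique.
#' @export
read_cell_annotation <- function(path) {
  ann <- read_tsv_file(path)
  if (!"barcode" %in% names(ann)) {
    stop_format("annotation file '%s' lacks required column 'barcode'", path)
  }
  if (anyDuplicated(ann$barcode)) {
    stop_format("annotation file '%s' has duplicate barcodes", path)
  }
  ann
}

#' Check an annotation table against a count matrix
#'
#' Every annotated barcode must exist among the matrix's cells.
#'
#' @param ann Annotation data.frame with a `barcode` column.
#' @param counts Count (or normalized) matrix with barcode colnames.
#' @return `ann`, invisibly.
#' @export
check_annotation <- function(ann, counts) {
  missing <- setdiff(ann$barcode, colnames(counts))
  if (length(missing)) {
    stop_format("%d annotated barcode(s) absent from the count matrix (e.g. '%s')",
                length(missing), missing[1])
  }
  invisible(ann)
}

#' Construct a gene set
#'
#' @param name Set label.
#' @param genes Character vector of gene symbols; must be non-empty and
#'   duplicate-free.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, genes) {
  if (!length(genes)) stop_format("gene set '%s' is empty", name)
  if (anyDuplicated(genes)) stop_format("gene set '%s' has duplicate symbols", name)
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets from a plain list or GMT file
#'
#' @param path File path. `"list"` format is one gene symbol per line; the set
#'   is named after the file. `"gmt"` rows are
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @param fmt `"auto"` (GMT when rows have >= 3 tab-separated fields),
#'   `"list"`, or `"gmt"`.
#' @return A named list of [gene_set()] objects (length 1 for `"list"`).
#'   Duplicate symbols within a set are collapsed with a warning; a set that is
#'   empty after parsing is an error.
#' @export
read_gene_set <- function(path, fmt = c("auto", "list", "gmt")) {
  fmt <- match.arg(fmt)
  lines <- read_lines_maybe_gz(path)
  lines <- lines[nzchar(trimws(lines))]
  if (fmt == "auto") {
    nfields <- lengths(strsplit(lines, "\t", fixed = TRUE))
    fmt <- if (length(lines) && all(nfields >= 3L)) "gmt" else "list"
  }
  if (fmt == "list") {
    name <- sub("\\.(txt|tsv|list)(\\.gz)?$", "", basename(path))
    sets <- list(make_deduped_set(name, trimws(lines)))
  } else {
    if (!length(lines)) stop_format("GMT file '%s' is empty", path)
    sets <- lapply(lines, function(row) {
      f <- strsplit(row, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3L) stop_format("GMT row with fewer than 3 fields in '%s'", path)
      make_deduped_set(f[1], f[-(1:2)])
    })
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

make_deduped_set <- function(name, genes) {
  genes <- genes[nzchar(genes)]
  if (anyDuplicated(genes)) {
    warning(sprintf("gene set '%s': %d duplicate symbol(s) collapsed",
                    name, sum(duplicated(genes))), call. = FALSE)
    genes <- unique(genes)
  }
  if (!length(genes)) stop_format("gene set '%s' is empty after parsing", name)
  gene_set(name, genes)
}

#' Read a ligand-receptor pair table
#'
#' Parses a TSV of directional ligand-to-receptor signaling pairs such as the
#' curated databases distributed by LR-resource repositories. Multi-subunit
#' complexes are encoded in a single field with subunits joined by separator
#' characters (`Tgfbr1_Tgfbr2`).
#'
#' @param path TSV file with a header row.
#' @param ligand_col,receptor_col Column names holding the ligand and receptor
#'   (complex) symbols. Missing columns are a format error.
#' @param pair_id_col Optional column with unique pair identifiers; when
#'   absent, ids are synthesized as `ligand->receptor`.
#' @param pathway_col Optional pathway label column.
#' @param subunit_sep Characters on which complex fields are split into
#'   subunits (default `_` and `&`).
#' @return A data.frame of class `lr_pair_table` with columns `pair_id`,
#'   `ligand`, `receptor`, `pathway`, and list-columns `ligand_subunits`,
#'   `receptor_subunits`. Direction is always ligand to receptor. Exact
#'   duplicate (ligand, receptor) rows are collapsed with a warning; rows with
#'   an empty ligand or receptor are an error listing the offending lines.
#' @export
read_lr_pairs <- function(path, ligand_col = "ligand", receptor_col = "receptor",
                          pair_id_col = NULL, pathway_col = NULL,
                          subunit_sep = c("_", "&")) {
  tab <- read_tsv_file(path)
  for (col in c(ligand_col, receptor_col, pair_id_col, pathway_col)) {
    if (!col %in% names(tab)) {
      stop_format("LR pair file '%s' lacks required column '%s'", path, col)
    }
  }
  lig <- trimws(as.character(tab[[ligand_col]]))
  rec <- trimws(as.character(tab[[receptor_col]]))
  bad <- which(!nzchar(lig) | !nzchar(rec) | is.na(lig) | is.na(rec))
  if (length(bad)) {
    stop_format("LR pair file '%s': empty ligand or receptor on data line(s) %s",
                path, paste(bad, collapse = ", "))
  }
  dup <- duplicated(paste(lig, rec, sep = "\r"))
  if (any(dup)) {
    warning(sprintf("%d exact duplicate ligand-receptor row(s) collapsed", sum(dup)),
            call. = FALSE)
  }
  keep <- !dup
  lig <- lig[keep]; rec <- rec[keep]
  pair_id <- if (!is.null(pair_id_col)) as.character(tab[[pair_id_col]])[keep] else
    paste0(lig, "\u2192", rec)
  if (anyDuplicated(pair_id)) {
    stop_format("LR pair file '%s': duplicate pair_id values after deduplication", path)
  }
  pathway <- if (!is.null(pathway_col)) as.character(tab[[pathway_col]])[keep] else
    rep(NA_character_, length(lig))
  lr_pair_table(pair_id, lig, rec, pathway, subunit_sep)
}

#' Construct an LR pair table from vectors
#'
#' @param pair_id Unique pair identifiers.
#' @param ligand,receptor Ligand / receptor (complex) symbol strings.
#' @param pathway Optional pathway labels.
#' @param subunit_sep Separator characters for complex subunits.
#' @return An `lr_pair_table` data.frame (see [read_lr_pairs()]).
#' @export
lr_pair_table <- function(pair_id, ligand, receptor, pathway = NULL,
                          subunit_sep = c("_", "&")) {
  split_subunits <- function(x) {
    rx <- paste0("[", paste(gsub("([][\\^-])", "\\\\\\1", subunit_sep), collapse = ""), "]")
    strsplit(x, rx)
  }
  lig_sub <- split_subunits(ligand)
  rec_sub <- split_subunits(receptor)
  if (any(lengths(lig_sub) < 1L) || any(lengths(rec_sub) < 1L)) {
    stop_format("every LR pair needs at least one ligand and one receptor subunit")
  }
  if (anyDuplicated(pair_id)) stop_format("pair_id values must be unique")
  out <- data.frame(pair_id = pair_id, ligand = ligand, receptor = receptor,
                    pathway = pathway %||% rep(NA_character_, length(pair_id)),
                    stringsAsFactors = FALSE)
  out$ligand_subunits <- lig_sub
  out$receptor_subunits <- rec_sub
  class(out) <- c("lr_pair_table", "data.frame")
  out
}
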