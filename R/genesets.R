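#' Gene-set collections
#'
#' A gene-set collection holds an ordered list of named gene sets (character
#' vectors of gene symbols), a collection kind (`"cell_signature"` or
#' `"go_bp"`), and a per-set category annotation. Cell-signature categories
#' are one of `lymphoid`, `myeloid`, `stem`, `stromal`, `other`; GO sets all
#' carry category `go_bp`.
#'
#' @param sets named list of character vectors; names are set identifiers,
#'   elements are gene symbols. Duplicate symbols within a set are removed.
#' @param kind `"cell_signature"` or `"go_bp"`.
#' @param categories optional named character vector mapping set names to
#'   categories; unnamed sets default to `"other"` (or `"go_bp"`).
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, kind = c("cell_signature", "go_bp"),
                                categories = NULL) {
  kind <- match.arg(kind)
  if (!is.list(sets))
    stop("`sets` must be a list of character vectors", call. = FALSE)
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every gene set must have a non-empty name", call. = FALSE)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    unique(g[nzchar(g)])
  })
  if (any(lengths(sets) == 0L))
    stop("gene set(s) with no genes: ",
         paste(nm[lengths(sets) == 0L], collapse = ", "), call. = FALSE)

  default_cat <- if (kind == "go_bp") "go_bp" else "other"
  cat_vec <- rep(default_cat, length(sets))
  names(cat_vec) <- nm
  if (!is.null(categories)) {
    categories <- categories[names(categories) %in% nm]
    valid <- c("lymphoid", "myeloid", "stem", "stromal", "other", "go_bp")
    bad <- setdiff(unique(categories), valid)
    if (length(bad))
      stop("unknown category value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    cat_vec[names(categories)] <- categories
  }
  structure(list(sets = sets, kind = kind, categories = cat_vec),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' @export
`[.gene_set_collection` <- function(x, i) {
  gene_set_collection(x$sets[i], kind = x$kind,
                      categories = x$categories[names(x$sets[i])])
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d %s set(s)\n", length(x), x$kind))
  if (length(x)) {
    sz <- lengths(x$sets)
    cat(sprintf("  set sizes: %d-%d (median %g)\n",
                min(sz), max(sz), stats::median(sz)))
    if (x$kind == "cell_signature")
      print(table(x$categories))
  }
  invisible(x)
}

#' Set sizes of a collection
#' @param coll a `gene_set_collection`.
#' @return named integer vector of set sizes.
#' @export
set_sizes <- function(coll) lengths(coll$sets)

#' Read a GMT gene-set file
#'
#' Parses the tab-separated GMT format (set name, description, then gene
#' symbols). Duplicate symbols within a line are dropped; empty gene fields
#' are ignored.
#'
#' @param path path to a GMT file (plain text or gzip).
#' @param kind collection kind, `"cell_signature"` or `"go_bp"`.
#' @param categories optional named character vector of set categories (see
#'   [gene_set_collection()]); typically from [read_category_table()].
#' @return a `gene_set_collection`.
#' @export
read_gmt <- function(path, kind = c("cell_signature", "go_bp"),
                     categories = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(gene_set_collection(structure(list(), names = character(0)),
                               kind = kind))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields",
                 short[1]), call. = FALSE)
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name(s) in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, kind = kind, categories = categories)
}

#' Write a collection to GMT
#' @param coll a `gene_set_collection`.
#' @param path output file path.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to the category).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- unname(coll$categories)
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(coll), descriptions, coll$sets)
  writeLines(unlist(lines, use.names = FALSE), path)
  invisible(path)
}

#' Read a two-column set-name / category table
#' @param path TSV with columns: set name, category (no header).
#' @return named character vector mapping set names to categories.
#' @export
read_category_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          quote = "", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("category table must have two tab-separated columns", call. = FALSE)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Filter gene sets by size
#'
#' Retains sets whose gene count lies within `[min_size, max_size]`
#' inclusive, preserving input order. Defaults drop sets with fewer than 15
#' or more than 350 genes, the band used for the GO biological-process
#' collection.
#'
#' @param coll a `gene_set_collection`.
#' @param min_size,max_size inclusive size bounds.
#' @return filtered `gene_set_collection`.
#' @export
filter_by_size <- function(coll, min_size = 15L, max_size = 350L) {
  stopifnot(min_size >= 1L, max_size >= min_size)
  keep <- lengths(coll$sets) >= min_size & lengths(coll$sets) <= max_size
  coll[which(keep)]
}

#' Restrict gene sets to a gene universe
#'
#' Intersects every set with `universe` (typically the measured,
#' prevalence-filtered genes of an expression matrix) so that overlap
#' statistics and median expression are computed over the same genes.
#'
#' @param coll a `gene_set_collection`.
#' @param universe character vector of gene symbols.
#' @param drop_empty drop sets that become empty (default `TRUE`).
#' @return restricted `gene_set_collection`.
#' @export
restrict_to_universe <- function(coll, universe, drop_empty = TRUE) {
  if (!length(universe))
    stop("`universe` must be non-empty", call. = FALSE)
  new_sets <- lapply(coll$sets, function(g) g[g %in% universe])
  keep <- if (drop_empty) lengths(new_sets) > 0L else rep(TRUE, length(new_sets))
  # assembled directly: with drop_empty = FALSE the result may legitimately
  # hold empty sets, which the constructor would reject
  structure(list(sets = new_sets[keep], kind = coll$kind,
                 categories = coll$categories[names(new_sets)[keep]]),
            class = "gene_set_collection")
}

non_solid_default <- c("pro-B cells",
                       "Hematopoietic stem cells",
                       "Common lymphoid progenitors")

#' Packaged cell-type signature collection
#'
#' Loads the 86-set cell-type signature collection shipped with the package.
#' The shipped collection is a SYNTHETIC stand-in: it reproduces the
#' structure of the published 86-signature resource (86 cell types; 40
#' lymphoid, 15 myeloid, 11 stem, 11 stromal and 9 other; set sizes inside
#' the 15-350 band; real cell-type names) but uses synthetic gene symbols
#' (SYNG####) because the curated marker table cannot be redistributed.
#' Supply your own GMT via [read_gmt()] for real analyses.
#'
#' @param exclude_non_solid drop cell types absent from solid tumor tissue
#'   (pro-B cells, hematopoietic stem cells, common lymphoid progenitors;
#'   see `inst/extdata/non_solid_tumor_cells.txt`, user-extensible).
#' @return a `gene_set_collection` of kind `"cell_signature"`.
#' @export
load_cell_signatures <- function(exclude_non_solid = FALSE) {
  gmt <- system.file("extdata", "cell_signatures_synthetic.gmt",
                     package = "InfilNet")
  cats <- system.file("extdata", "cell_signature_categories.tsv",
                      package = "InfilNet")
  if (!nzchar(gmt) || !nzchar(cats))
    stop("packaged signature collection not found; supply your own GMT via ",
         "read_gmt()", call. = FALSE)
  coll <- read_gmt(gmt, kind = "cell_signature",
                   categories = read_category_table(cats))
  if (exclude_non_solid) {
    excl <- non_solid_cell_types()
    coll <- coll[which(!names(coll) %in% excl)]
  }
  coll
}

#' Cell types excluded from solid-tumor analyses
#'
#' The documented exclusion list: cell types not expected in solid tumor
#' tissue. Read from `inst/extdata/non_solid_tumor_cells.txt` (one name per
#' line, `#` comments allowed) so users can extend it.
#'
#' @return character vector of cell-type names.
#' @export
non_solid_cell_types <- function() {
  path <- system.file("extdata", "non_solid_tumor_cells.txt",
                      package = "InfilNet")
  if (!nzchar(path)) return(non_solid_default)
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Packaged GO biological-process collection
#'
#' Loads the synthetic GO-BP stand-in collection shipped with the package
#' (200 terms, sizes within the 15-350 band, sharing genes with the packaged
#' signature universe). For real analyses supply a GO-BP GMT (e.g. from
#' MSigDB) via [read_gmt()] and size-filter it with [filter_by_size()].
#'
#' @return a `gene_set_collection` of kind `"go_bp"`.
#' @export
load_go_bp <- function() {
  gmt <- system.file("extdata", "go_bp_synthetic.gmt", package = "InfilNet")
  if (!nzchar(gmt))
    stop("packaged GO-BP collection not found; supply your own GMT via ",
         "read_gmt()", call. = FALSE)
  read_gmt(gmt, kind = "go_bp")
}
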