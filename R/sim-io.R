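#' Write a synthetic dataset to disk
#'
#' Emits one GFF3-like gene-order file per species plus TSV tables for
#' families, reaction-type labels and GO annotations, and the species tree
#' as newick. The files round-trip through [read_gene_tables()],
#' [read_family_table()], [read_type_labels()] and [read_go_annotations()].
#'
#' Gene coordinates are synthesized from ordinal ranks (gene `i` occupies
#' `[1000 i + 1, 1000 i + 900]`): only the order and strand carry
#' information downstream.
#'
#' @param dataset a `synthetic_dataset`.
#' @param directory output directory (created if missing).
#' @return invisibly, the character vector of files written.
#' @export
emit_gene_tables <- function(dataset, directory) {
  if (!inherits(dataset, "synthetic_dataset"))
    stop("'dataset' must be a synthetic_dataset")
  if (nrow(dataset$gene_table) == 0L)
    stop("refusing to write an empty dataset")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  files <- character(0)
  gt <- dataset$gene_table
  for (sp in unique(gt$species)) {
    sub <- gt[gt$species == sp, , drop = FALSE]
    path <- file.path(directory, paste0(sp, ".gff"))
    start <- 1000L * sub$pos + 1L
    lines <- sprintf("%s\tsyntnet\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     sub$chromosome, start, start + 899L, sub$strand,
                     sub$gene)
    writeLines(lines, path)
    files <- c(files, path)
  }
  fam_path <- file.path(directory, "families.tsv")
  write_family_table(family_assignment(dataset$truth_families, "truth"),
                     fam_path)
  type_path <- file.path(directory, "types.tsv")
  write_tsv_mapping(dataset$type_labels, type_path)
  go_path <- file.path(directory, "go.tsv")
  go_flat <- vapply(dataset$go_annotations, paste, character(1),
                    collapse = ";")
  write_tsv_mapping(go_flat, go_path)
  tree_path <- file.path(directory, "species_tree.nwk")
  ape::write.tree(dataset$tree, tree_path)
  invisible(c(files, fam_path, type_path, go_path, tree_path))
}

write_tsv_mapping <- function(x, path) {
  writeLines(paste(names(x), unname(x), sep = "\t"), path)
  invisible(path)
}

#' Read per-species gene-order tables
#'
#' Accepts GFF3-like files (one per species; only rows of type `gene` are
#' used, ordered by start coordinate within each seqid) and returns the
#' package's standard gene table.
#'
#' @param paths named character vector of file paths; names are taken as
#'   species identifiers (defaults to file base names).
#' @return data.frame with columns gene, species, chromosome, pos (0-based
#'   ordinal within chromosome), strand.
#' @export
read_gene_tables <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  out <- list()
  for (sp in names(paths)) {
    path <- paths[[sp]]
    if (!file.exists(path)) stop("gene table not found: ", path)
    raw <- readLines(path)
    raw <- raw[!grepl("^#", raw) & nzchar(raw)]
    if (length(raw) == 0L) next
    parts <- strsplit(raw, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) < 9L)
    if (length(bad))
      stop("malformed GFF line ", bad[1], " in ", path)
    df <- data.frame(
      chromosome = vapply(parts, `[[`, character(1), 1L),
      type = vapply(parts, `[[`, character(1), 3L),
      start = as.numeric(vapply(parts, `[[`, character(1), 4L)),
      strand = vapply(parts, `[[`, character(1), 7L),
      attr = vapply(parts, `[[`, character(1), 9L),
      stringsAsFactors = FALSE)
    df <- df[df$type == "gene", , drop = FALSE]
    id <- sub("^.*ID=([^;]+).*$", "\\1", df$attr)
    df <- df[order(df$chromosome, df$start), , drop = FALSE]
    pos <- unlist(lapply(split(seq_len(nrow(df)), df$chromosome),
                         function(i) seq_along(i) - 1L), use.names = FALSE)
    out[[sp]] <- data.frame(gene = id[order(df$chromosome, df$start)],
                            species = sp,
                            chromosome = sort(df$chromosome),
                            pos = pos, strand = df$strand[order(df$chromosome,
                                                                df$start)],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene = character(0), species = character(0),
                      chromosome = character(0), pos = integer(0),
                      strand = character(0))
  rownames(res) <- NULL
  res
}

#' Read gene -> reaction-type labels
#'
#' @param path two-column TSV (gene, type label).
#' @return named character vector gene -> type.
#' @export
read_type_labels <- function(path) read_two_col(path, "type label")

#' Read gene -> GO annotation table
#'
#' @param path two-column TSV (gene, semicolon-separated GO terms).
#' @return named list gene -> character vector of GO terms.
#' @export
read_go_annotations <- function(path) {
  flat <- read_two_col(path, "GO annotation")
  lapply(flat, function(s) strsplit(s, ";", fixed = TRUE)[[1]])
}

read_two_col <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) return(setNames(character(0), character(0)))
  parts <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad)) stop("malformed ", what, " line ", bad[1], " in ", path)
  gene <- vapply(parts, `[[`, character(1), 1L)
  if (gene[1] == "gene") {  # tolerate a header row
    parts <- parts[-1]; gene <- gene[-1]
  }
  if (anyDuplicated(gene))
    stop("duplicate gene in ", what, " table: ", gene[duplicated(gene)][1])
  setNames(vapply(parts, `[[`, character(1), 2L), gene)
}
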