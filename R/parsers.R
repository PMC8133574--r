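#' Parse an MCScanX .collinearity file
#'
#' Reads the `## Alignment` block format: a header line
#' `## Alignment k: score=... e_value=... N=... chrA&chrB plus|minus`
#' followed by one tab-separated anchor line per gene pair. Comment lines
#' (`#` parameter preamble) are skipped. Anchor lines outside any block are
#' an error.
#'
#' @param path file path.
#' @param provenance family-clustering provenance to record on the blocks.
#' @return `collinear_blocks` data.frame (positions are unknown to the
#'   format and set to NA; method label detector = `"mcscanx"`).
#' @export
parse_mcscanx_collinearity <- function(path, provenance = "imported") {
  if (!file.exists(path)) stop("collinearity file not found: ", path)
  raw <- readLines(path)
  out <- list()
  cur <- NULL
  hdr_re <- paste0("^## Alignment ([0-9]+): score=([0-9.eE+-]+)",
                   "\\s+e_value=\\S+\\s+N=[0-9]+\\s+(\\S+)&(\\S+)\\s+",
                   "(plus|minus)\\s*$")
  flush <- function(cur) {
    if (is.null(cur) || length(cur$genes_a) == 0L) return(NULL)
    data.frame(block = cur$id + 1L, gene_a = cur$genes_a, pos_a = NA_integer_,
               gene_b = cur$genes_b, pos_b = NA_integer_,
               family = NA_character_,
               orientation = if (cur$orient == "plus") 1L else -1L,
               score = cur$score, chrom_a = cur$chrom_a,
               chrom_b = cur$chrom_b, stringsAsFactors = FALSE)
  }
  for (ln in seq_along(raw)) {
    line <- raw[ln]
    if (grepl("^## Alignment", line)) {
      m <- regmatches(line, regexec(hdr_re, line))[[1]]
      if (length(m) == 0L)
        stop("malformed alignment header at line ", ln, ": ", line)
      out[[length(out) + 1L]] <- flush(cur)
      cur <- list(id = as.integer(m[2]), score = as.numeric(m[3]),
                  chrom_a = m[4], chrom_b = m[5], orient = m[6],
                  genes_a = character(0), genes_b = character(0))
    } else if (grepl("^#", line) || !nzchar(trimws(line))) {
      next
    } else {
      if (is.null(cur))
        stop("anchor line outside any alignment block at line ", ln)
      toks <- strsplit(trimws(line), "\t")[[1]]
      # format: "  k-  i:\tgeneA\tgeneB\t  e" (first token may hold index)
      toks <- toks[nzchar(toks)]
      if (length(toks) < 3L)
        stop("malformed anchor line at line ", ln, ": ", line)
      cur$genes_a <- c(cur$genes_a, toks[2])
      cur$genes_b <- c(cur$genes_b, toks[3])
    }
  }
  out[[length(out) + 1L]] <- flush(cur)
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    res <- empty_blocks()
    res$chrom_a <- character(0); res$chrom_b <- character(0)
    res$detector <- character(0); res$provenance <- character(0)
    return(res)
  }
  res <- do.call(rbind, out)
  res$block <- match(res$block, unique(res$block))
  res$detector <- "mcscanx"
  res$provenance <- provenance
  rownames(res) <- NULL
  class(res) <- c("collinear_blocks", "data.frame")
  res
}

#' Write blocks in MCScanX .collinearity format
#'
#' @param blocks a `collinear_blocks` data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mcscanx_collinearity <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("############### Parameters ###############", con)
  writeLines("# written by syntnet", con)
  for (b in unique(blocks$block)) {
    sub <- blocks[blocks$block == b, , drop = FALSE]
    ca <- if ("chrom_a" %in% names(sub)) sub$chrom_a[1] else "chrU"
    cb <- if ("chrom_b" %in% names(sub)) sub$chrom_b[1] else "chrU"
    writeLines(sprintf("## Alignment %d: score=%.1f e_value=0 N=%d %s&%s %s",
                       b - 1L, sub$score[1], nrow(sub), ca, cb,
                       if (sub$orientation[1] >= 0) "plus" else "minus"),
               con)
    writeLines(sprintf("%3d-%3d:\t%s\t%s\t      0", b - 1L,
                       seq_len(nrow(sub)) - 1L, sub$gene_a, sub$gene_b),
               con)
  }
  invisible(path)
}

#' Parse i-ADHoRe output tables
#'
#' Reads `multiplicons.txt` and the anchor-pair table
#' (`anchorpoints.txt`, or `multiplicon_pairs.txt` if that is what the
#' run produced) from an i-ADHoRe output directory. Only level-2
#' multiplicons (pairwise comparisons, as under `level_2_only=true`) are
#' converted to blocks.
#'
#' @param directory i-ADHoRe output directory.
#' @param provenance family-clustering provenance to record.
#' @return `collinear_blocks` data.frame (method label detector =
#'   `"iadhore"`).
#' @export
parse_iadhore_output <- function(directory, provenance = "imported") {
  mp_path <- file.path(directory, "multiplicons.txt")
  if (!file.exists(mp_path))
    stop("multiplicons.txt not found in ", directory)
  ap_path <- file.path(directory, "anchorpoints.txt")
  if (!file.exists(ap_path))
    ap_path <- file.path(directory, "multiplicon_pairs.txt")
  if (!file.exists(ap_path))
    stop("anchorpoints.txt / multiplicon_pairs.txt not found in ",
         directory)
  mp <- utils::read.delim(mp_path, stringsAsFactors = FALSE)
  ap <- utils::read.delim(ap_path, stringsAsFactors = FALSE)
  if (!"level" %in% names(mp)) stop("multiplicons table lacks 'level'")
  keep_ids <- mp$id[mp$level == 2L]
  mcol <- intersect(c("multiplicon", "multiplicon_id"), names(ap))[1]
  gxcol <- intersect(c("gene_x", "gene_1"), names(ap))[1]
  gycol <- intersect(c("gene_y", "gene_2"), names(ap))[1]
  if (is.na(mcol) || is.na(gxcol) || is.na(gycol))
    stop("anchor-pair table lacks multiplicon/gene columns")
  ap <- ap[ap[[mcol]] %in% keep_ids, , drop = FALSE]
  if (nrow(ap) == 0L) {
    res <- empty_blocks()
    res$chrom_a <- character(0); res$chrom_b <- character(0)
    res$detector <- character(0); res$provenance <- character(0)
    return(res)
  }
  ids <- unique(ap[[mcol]])
  out <- lapply(seq_along(ids), function(k) {
    sub <- ap[ap[[mcol]] == ids[k], , drop = FALSE]
    info <- mp[mp$id == ids[k], , drop = FALSE]
    data.frame(block = k, gene_a = sub[[gxcol]], pos_a = NA_integer_,
               gene_b = sub[[gycol]], pos_b = NA_integer_,
               family = NA_character_, orientation = 1L,
               score = as.numeric(nrow(sub)),
               chrom_a = if ("list_x" %in% names(info)) info$list_x[1]
                         else NA_character_,
               chrom_b = if ("list_y" %in% names(info)) info$list_y[1]
                         else NA_character_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$detector <- "iadhore"
  res$provenance <- provenance
  rownames(res) <- NULL
  class(res) <- c("collinear_blocks", "data.frame")
  res
}

#' Write / read the internal block table
#'
#' One anchor per row with its block id and metadata; a plain TSV that
#' round-trips through `read_blocks()`.
#'
#' @param blocks a `collinear_blocks` data.frame.
#' @param path file path.
#' @return `read_blocks`: a `collinear_blocks` data.frame.
#' @export
write_blocks <- function(blocks, path) {
  utils::write.table(as.data.frame(blocks), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blocks
#' @export
read_blocks <- function(path) {
  if (!file.exists(path)) stop("block table not found: ", path)
  res <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(res) <- c("collinear_blocks", "data.frame")
  res
}
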