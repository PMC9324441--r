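#' Retroelement insertion matrices
#'
#' An `ri_matrix` holds a taxa-by-loci table of retroelement insertion (RI)
#' presence/absence characters: `1` = insertion present at the orthologous
#' locus, `0` = absent, `NA` = missing (locus not recoverable from the
#' genome assembly).  Each character can be reduced to a single bipartition
#' separating present-coded from absent-coded taxa, the "single-bipartition
#' gene tree" that quartet-based coalescent methods consume.
#'
#' @param states integer or numeric matrix (taxa x loci) with entries 0, 1
#'   or `NA`; rownames are taxon labels.
#' @param taxa optional character vector of taxon labels (defaults to
#'   rownames of `states`).
#' @param locus_ids optional locus identifiers; default 1-based column
#'   indices.
#' @return An object of class `ri_matrix`.
#' @export
ri_matrix <- function(states, taxa = rownames(states), locus_ids = NULL) {
  states <- as.matrix(states)
  if (is.null(taxa)) stop("taxon labels required (rownames or `taxa`)")
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  if (length(taxa) != nrow(states)) stop("length(taxa) != nrow(states)")
  storage.mode(states) <- "integer"
  bad <- !(states %in% c(0L, 1L) | is.na(states))
  if (any(bad)) {
    w <- which(matrix(bad, nrow(states)), arr.ind = TRUE)[1L, ]
    stop("invalid state at taxon '", taxa[w[1L]], "', locus ", w[2L],
         ": states must be 0, 1 or missing")
  }
  if (is.null(locus_ids)) locus_ids <- seq_len(ncol(states))
  if (length(locus_ids) != ncol(states)) stop("length(locus_ids) != ncol(states)")
  rownames(states) <- taxa
  colnames(states) <- as.character(locus_ids)
  structure(list(states = states, taxa = taxa, locus_ids = locus_ids),
            class = "ri_matrix")
}

#' @export
print.ri_matrix <- function(x, ...) {
  cat("RI matrix:", length(x$taxa), "taxa x", ncol(x$states), "characters;",
      sum(is.na(x$states)), "missing cells\n")
  invisible(x)
}

#' @export
dim.ri_matrix <- function(x) dim(x$states)

parse_symbols <- function(ch, where) {
  out <- rep(NA_integer_, length(ch))
  out[ch == "1"] <- 1L
  out[ch == "0"] <- 0L
  bad <- !(ch %in% c("0", "1", "?"))
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("parse error at ", where, ", column ", i, ": unknown symbol '",
         ch[i], "' (expected 0, 1 or ?)")
  }
  out
}

#' Read an RI presence/absence matrix
#'
#' Reads a taxa-by-loci binary character matrix with symbols `1` (present),
#' `0` (absent) and `?` (missing) from either a NEXUS file
#' (`datatype=standard`) or a TSV file whose first column is the taxon
#' label, with one character per remaining column (header row optional).
#'
#' @param path file path.
#' @param format `"tsv"` or `"nexus"`; default guessed from the extension.
#' @return An [ri_matrix()].
#' @export
read_ri_matrix <- function(path, format = c("auto", "tsv", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE)) "nexus" else "tsv"
  }
  if (format == "nexus") {
    dat <- ape::read.nexus.data(path)
    taxa <- names(dat)
    if (anyDuplicated(taxa)) {
      stop("duplicate taxon label in NEXUS file: ",
           taxa[duplicated(taxa)][1L])
    }
    rows <- lapply(taxa, function(tx) parse_symbols(toupper(dat[[tx]]), tx))
    nl <- lengths(rows)
    if (length(unique(nl)) != 1L) stop("unequal character counts across taxa")
    return(ri_matrix(do.call(rbind, rows), taxa = taxa))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- fields[[1L]]
  header <- length(first) > 1L && !all(first[-1L] %in% c("0", "1", "?"))
  locus_ids <- NULL
  if (header) {
    locus_ids <- first[-1L]
    fields <- fields[-1L]
  }
  taxa <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon label: ", taxa[duplicated(taxa)][1L])
  }
  rows <- lapply(seq_along(fields), function(i)
    parse_symbols(fields[[i]][-1L], paste0("taxon '", taxa[i], "'")))
  nl <- lengths(rows)
  if (length(unique(nl)) != 1L) stop("ragged rows: unequal character counts")
  ri_matrix(do.call(rbind, rows), taxa = taxa, locus_ids = locus_ids)
}

#' Write an RI matrix
#'
#' @param m an [ri_matrix()].
#' @param path output file.
#' @param format `"tsv"` or `"nexus"` (datatype=standard, symbols "01",
#'   missing "?").
#' @export
write_ri_matrix <- function(m, path, format = c("tsv", "nexus")) {
  format <- match.arg(format)
  sym <- ifelse(is.na(m$states), "?", as.character(m$states))
  if (format == "tsv") {
    lines <- vapply(seq_along(m$taxa), function(i)
      paste(c(m$taxa[i], sym[i, ]), collapse = "\t"), "")
    writeLines(c(paste(c("taxon", as.character(m$locus_ids)), collapse = "\t"),
                 lines), path)
  } else {
    seqs <- apply(sym, 1L, paste, collapse = "")
    lines <- c("#NEXUS", "BEGIN DATA;",
               paste0("  DIMENSIONS NTAX=", length(m$taxa),
                      " NCHAR=", ncol(m$states), ";"),
               "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
               "  MATRIX",
               paste0("    ", m$taxa, "  ", seqs),
               "  ;", "END;")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Reduce RI characters to bipartitions
#'
#' Each character becomes a two-sided taxon split: taxa coded present vs.
#' taxa coded absent, with missing-coded taxa excluded.  Characters whose
#' present or absent side has fewer than `min_side` taxa are dropped and
#' reported; with `min_side = 2` the retained set is exactly the characters
#' that induce at least one quartet (the quartet-informative characters).
#'
#' @param m an [ri_matrix()].
#' @param min_side minimum taxa required on each side (default 1).
#' @return A list of class `ri_bipartitions`; each element has `locus_id`,
#'   `present`, `absent` and `excluded` taxon labels.  Dropped characters
#'   are reported in attribute `dropped` (data frame).
#' @export
to_bipartitions <- function(m, min_side = 1L) {
  stopifnot(inherits(m, "ri_matrix"), min_side >= 1L)
  out <- list()
  dropped <- list()
  for (j in seq_len(ncol(m$states))) {
    col <- m$states[, j]
    pres <- m$taxa[!is.na(col) & col == 1L]
    abs_ <- m$taxa[!is.na(col) & col == 0L]
    if (length(pres) >= min_side && length(abs_) >= min_side) {
      out[[length(out) + 1L]] <- list(
        locus_id = m$locus_ids[j],
        present = pres, absent = abs_,
        excluded = m$taxa[is.na(col)])
    } else {
      dropped[[length(dropped) + 1L]] <-
        data.frame(locus_id = m$locus_ids[j],
                   n_present = length(pres), n_absent = length(abs_))
    }
  }
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(locus_id = integer(), n_present = integer(), n_absent = integer())
  attr(out, "taxa") <- m$taxa
  class(out) <- "ri_bipartitions"
  out
}

#' @export
print.ri_bipartitions <- function(x, ...) {
  cat("RI bipartitions:", length(x), "retained,",
      nrow(attr(x, "dropped")), "dropped\n")
  invisible(x)
}

#' Reconstruct a character column from a bipartition
#'
#' Inverse of [to_bipartitions()] for a single character: present taxa get
#' 1, absent taxa 0, excluded taxa `NA`.
#'
#' @param bp one element of an `ri_bipartitions` list.
#' @param taxa full taxon vector.
#' @export
bipartition_to_character <- function(bp, taxa) {
  col <- rep(NA_integer_, length(taxa))
  col[match(bp$present, taxa)] <- 1L
  col[match(bp$absent, taxa)] <- 0L
  stats::setNames(col, taxa)
}

#' Missing-data summary
#'
#' Per-taxon counts of missing (`?`) entries, their mean across taxa, and
#' the mean as a fraction of the total character count.
#'
#' @param m an [ri_matrix()].
#' @return A `missing_summary` object: `counts` (named integer), `mean`,
#'   `fraction`, `n_loci`.
#' @export
missing_summary <- function(m) {
  stopifnot(inherits(m, "ri_matrix"))
  counts <- rowSums(is.na(m$states))
  structure(list(counts = stats::setNames(as.integer(counts), m$taxa),
                 mean = mean(counts),
                 fraction = mean(counts) / ncol(m$states),
                 n_loci = ncol(m$states)),
            class = "missing_summary")
}

#' @export
print.missing_summary <- function(x, ...) {
  cat(sprintf("Missing data: mean %.1f of %d characters per taxon (%.1f%%)\n",
              x$mean, x$n_loci, 100 * x$fraction))
  invisible(x)
}

#' Write bipartitions as single-split newick trees
#'
#' One newick line per bipartition: an unrooted tree with a single internal
#' edge separating the present side from the absent side; excluded
#' (missing) taxa are omitted.
#'
#' @param bps an `ri_bipartitions` list.
#' @param path output file.
#' @export
write_bipartition_newick <- function(bps, path) {
  if (!length(bps)) stop("empty bipartition list")
  grp <- function(x) {
    if (length(x) == 1L) x else paste0("(", paste(x, collapse = ","), ")")
  }
  lines <- vapply(bps, function(bp)
    paste0("(", grp(bp$present), ",", grp(bp$absent), ");"), "")
  writeLines(lines, path)
  invisible(path)
}
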