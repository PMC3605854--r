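# Readers and writers for the standard plain-text formats: FASTA alignments
# (via ape) and Genepop microsatellite tables (no Genepop reader ships with
# the installed stack, so the dialect-detecting parser lives here).

#' Read a FASTA alignment
#'
#' Preserves record order, uppercases sequences, and validates equal
#' lengths; an empty file yields an empty alignment with a warning.
#'
#' @param path FASTA file.
#' @return a [alignment()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0 ||
      !any(startsWith(trimws(readLines(path, warn = FALSE)), ">"))) {
    warning("empty FASTA file: ", path)
    return(alignment(character(0)))
  }
  recs <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(recs), paste, character(1),
                         collapse = ""))
  alignment(setNames(seqs, names(recs)))
}

#' Write a FASTA alignment
#'
#' Sequences wrapped at 70 columns.
#'
#' @param aln a [alignment()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seqs <- as.character(aln)
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[i]
    starts <- seq(1, nchar(s), by = 70)
    writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
  }
  invisible(path)
}

#' Read a Genepop microsatellite file
#'
#' Auto-detects 2- versus 3-digit allele coding; `000`/`00` alleles are
#' recorded as missing. Each individual record carries two gene copies per
#' locus; gene copies are labelled `<id>/1` and `<id>/2`.
#'
#' @param path Genepop file.
#' @param pop_labels optional labels for the POP blocks (default
#'   `pop1`, `pop2`, ...).
#' @return list with `str` (a [str_dataset()]) and `popmap` (individuals).
#' @export
read_genepop <- function(path, pop_labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("malformed Genepop file: too short")
  lines <- lines[nzchar(trimws(lines))]
  body <- lines[-1]  # first line is the title
  pop_rows <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_rows) == 0) stop("malformed Genepop file: no POP block")
  loci_lines <- body[seq_len(pop_rows[1] - 1)]
  loci <- unlist(strsplit(paste(loci_lines, collapse = ","), ","))
  loci <- trimws(loci); loci <- loci[nzchar(loci)]
  n_loci <- length(loci)
  if (is.null(pop_labels)) pop_labels <- paste0("pop", seq_along(pop_rows))
  ids <- character(0); pops <- character(0)
  rows <- list()
  blocks <- c(pop_rows, length(body) + 1)
  for (b in seq_along(pop_rows)) {
    for (li in seq(blocks[b] + 1, blocks[b + 1] - 1)) {
      if (li > length(body)) break
      line <- body[li]
      parts <- strsplit(line, ",")[[1]]
      if (length(parts) < 2)
        stop("malformed Genepop individual record at line ", li + 1,
             ": missing comma")
      id <- trimws(parts[1])
      genos <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                        "\\s+")[[1]]
      if (length(genos) != n_loci)
        stop("locus count mismatch at line ", li + 1, ": got ",
             length(genos), ", expected ", n_loci)
      width <- unique(nchar(genos))
      if (length(width) != 1 || !width %in% c(4, 6))
        stop("unrecognized allele coding at line ", li + 1)
      half <- width / 2
      a1 <- as.integer(substr(genos, 1, half))
      a2 <- as.integer(substr(genos, half + 1, width))
      a1[a1 == 0] <- NA; a2[a2 == 0] <- NA
      ids <- c(ids, id); pops <- c(pops, pop_labels[b])
      rows[[length(rows) + 1]] <- a1
      rows[[length(rows) + 1]] <- a2
    }
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- loci
  labels <- paste0(rep(ids, each = 2), "/", rep(1:2, length(ids)))
  str <- structure(mat, class = c("coalabc_str", "matrix", "array"))
  storage.mode(str) <- "integer"
  rownames(str) <- labels
  list(str = str,
       popmap = data.frame(id = ids, population = pops,
                           stringsAsFactors = FALSE))
}

#' Write a Genepop microsatellite file
#'
#' 3-digit allele coding, one POP block per population, two gene copies per
#' individual record; missing alleles written as `000`.
#'
#' @param str a [str_dataset()] with `<id>/1`, `<id>/2` row labels.
#' @param popmap population map for the individuals.
#' @param path output file.
#' @param title header line.
#' @return invisibly, `path`.
#' @export
write_genepop <- function(str, popmap, path, title = "coalabc microsatellite data") {
  ids <- unique(sub("/[12]$", "", rownames(str)))
  pop <- popmap$population[match(ids, popmap$id)]
  if (anyNA(pop)) stop("individuals missing from population map")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(colnames(str), con)
  fmt <- function(x) ifelse(is.na(x), "000", sprintf("%03d", x))
  for (p in unique(pop)) {
    writeLines("POP", con)
    for (id in ids[pop == p]) {
      a1 <- unclass(str)[paste0(id, "/1"), ]
      a2 <- unclass(str)[paste0(id, "/2"), ]
      writeLines(paste0(id, " , ", paste0(fmt(a1), fmt(a2), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
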