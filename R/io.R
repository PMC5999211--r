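# Reading and writing genotype/phenotype tables (tabular and GenePop
# dialects), missing-data filters, and duplicate-genotype detection.

#' Write an individual table with genotypes
#'
#' Tab-separated text: metadata columns (\code{id}, \code{sex}, \code{area},
#' \code{year}, \code{cl}, \code{cw}) followed by two columns per locus
#' (\code{<locus>.1}, \code{<locus>.2}) holding allele labels, with 0 coding
#' a missing allele.
#'
#' @param individuals data.frame of individual records.
#' @param genotypes genotype matrix with rownames matching
#'   \code{individuals$id}.
#' @param path output file.
#' @export
write_individuals <- function(individuals, genotypes, path) {
  g <- genotypes[match(individuals$id, rownames(genotypes)), , drop = FALSE]
  g[is.na(g)] <- 0L
  out <- cbind(individuals, as.data.frame(g))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an individual table with genotypes
#'
#' Counterpart of [write_individuals()]. Rows with malformed genotype
#' entries (alleles absent from the panel) are reported with their line
#' numbers.
#'
#' @param path input file.
#' @param panel the \code{locus_panel} the genotype columns must match.
#' @return List with \code{individuals} (metadata data.frame) and
#'   \code{genotypes} (integer matrix, \code{NA} = missing).
#' @export
read_individuals <- function(path, panel) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  gcols <- as.vector(vapply(locus_names(panel),
                            function(nm) paste0(nm, c(".1", ".2")),
                            character(2)))
  missing_cols <- setdiff(gcols, colnames(tab))
  if (length(missing_cols))
    stop("header does not match panel; missing columns: ",
         paste(missing_cols, collapse = ", "))
  g <- as.matrix(tab[, gcols, drop = FALSE])
  storage.mode(g) <- "integer"
  bad <- character(0)
  for (l in seq_len(n_loci(panel))) {
    loc <- panel[[l]]
    cols <- locus_cols(l)
    vals <- g[, cols]
    unknown <- !(vals %in% c(0L, loc$alleles))
    if (any(unknown)) {
      rows <- unique(which(matrix(unknown, ncol = 2), arr.ind = TRUE)[, 1])
      bad <- c(bad, paste0(loc$name, " (line ",
                           paste(rows + 1L, collapse = ","), ")"))
    }
  }
  if (length(bad))
    stop("unknown alleles at locus ", paste(bad, collapse = "; "))
  g[g == 0L] <- NA_integer_
  rownames(g) <- tab$id
  meta <- tab[, setdiff(colnames(tab), gcols), drop = FALSE]
  list(individuals = meta, genotypes = g)
}

#' Write genotypes in GenePop format
#'
#' Three-digit allele codes (the allele's index within the panel's allele
#' list; 000 = missing), one POP block per group, comma after each
#' individual id.
#'
#' @param genotypes genotype matrix (rownames = ids).
#' @param groups group label per individual (defines POP blocks).
#' @param panel the \code{locus_panel}.
#' @param path output file.
#' @param title first line of the file.
#' @export
write_genepop <- function(genotypes, groups, panel, path,
                          title = "matesel genotype export") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(locus_names(panel), con)
  groups <- factor(groups, levels = unique(groups))  # first-appearance order
  for (g in levels(groups)) {
    writeLines("POP", con)
    rows <- which(groups == g)
    for (r in rows) {
      codes <- vapply(seq_len(n_loci(panel)), function(l) {
        a <- genotypes[r, locus_cols(l)]
        idx <- match(a, panel[[l]]$alleles)
        idx[is.na(idx)] <- 0L
        sprintf("%03d%03d", idx[1], idx[2])
      }, character(1))
      writeLines(paste0(rownames(genotypes)[r], " ,  ",
                        paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read genotypes from GenePop format
#'
#' @param path input file written by [write_genepop()] (or any GenePop file
#'   whose 3-digit codes index the panel's allele lists).
#' @param panel the \code{locus_panel}.
#' @return List with \code{genotypes} (matrix, rownames = ids) and
#'   \code{groups} (POP block index per individual).
#' @export
read_genepop <- function(path, panel) {
  lines <- readLines(path)
  L <- n_loci(panel)
  hdr <- lines[2:(L + 1)]
  if (!identical(trimws(hdr), locus_names(panel)))
    stop("locus list does not match panel")
  body <- lines[-(1:(L + 1))]
  ids <- character(0); grp <- integer(0)
  rows <- list()
  pop <- 0L
  for (ln in seq_along(body)) {
    line <- trimws(body[ln])
    if (!nzchar(line)) next
    if (toupper(line) == "POP") { pop <- pop + 1L; next }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) != 2) stop("malformed GenePop line ", ln + L + 1)
    id <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
    if (length(codes) != L)
      stop("line ", ln + L + 1, ": expected ", L, " genotype codes")
    g <- integer(2L * L)
    for (l in seq_len(L)) {
      i1 <- as.integer(substr(codes[l], 1, 3))
      i2 <- as.integer(substr(codes[l], 4, 6))
      k <- length(panel[[l]]$alleles)
      if (i1 > k || i2 > k)
        stop("line ", ln + L + 1, ": allele code out of range at locus ",
             panel[[l]]$name)
      g[locus_cols(l)] <- c(
        if (i1 == 0L) NA_integer_ else panel[[l]]$alleles[i1],
        if (i2 == 0L) NA_integer_ else panel[[l]]$alleles[i2])
    }
    ids <- c(ids, id); grp <- c(grp, pop)
    rows[[length(rows) + 1L]] <- g
  }
  geno <- do.call(rbind, rows)
  rownames(geno) <- ids
  colnames(geno) <- as.vector(vapply(locus_names(panel),
                                     function(nm) paste0(nm, c(".1", ".2")),
                                     character(2)))
  list(genotypes = geno, groups = grp)
}

#' Read a dataset of adults and broods
#'
#' Loads an adult table and a brood (egg) table written with
#' [write_individuals()]-style columns; the brood file must carry
#' \code{egg_id} and \code{mother_id} columns.
#'
#' @param adults_path path to the adult table.
#' @param broods_path path to the egg table.
#' @param panel the \code{locus_panel}.
#' @return List with \code{individuals}, \code{genotypes}, \code{eggs}
#'   (metadata) and \code{egg_genotypes}.
#' @export
read_dataset <- function(adults_path, broods_path, panel) {
  ad <- read_individuals(adults_path, panel)
  tab <- utils::read.table(broods_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("egg_id", "mother_id") %in% colnames(tab)))
    stop("brood file must contain egg_id and mother_id columns")
  tmp <- tempfile(); on.exit(unlink(tmp))
  tab2 <- tab
  colnames(tab2)[colnames(tab2) == "egg_id"] <- "id"
  utils::write.table(tab2, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  eg <- read_individuals(tmp, panel)
  list(individuals = ad$individuals, genotypes = ad$genotypes,
       eggs = data.frame(egg_id = tab$egg_id, mother_id = tab$mother_id,
                         stringsAsFactors = FALSE),
       egg_genotypes = eg$genotypes)
}

#' Count missing loci per individual
#'
#' A locus counts as missing when either of its two alleles is missing.
#'
#' @param genotypes genotype matrix.
#' @return Integer vector of missing-locus counts, named by individual.
#' @export
missing_loci <- function(genotypes) {
  L <- ncol(genotypes) / 2
  miss <- vapply(seq_len(L), function(l)
    !stats::complete.cases(genotypes[, locus_cols(l), drop = FALSE]),
    logical(nrow(genotypes)))
  if (is.null(dim(miss))) miss <- matrix(miss, nrow = 1)
  out <- rowSums(miss)
  names(out) <- rownames(genotypes)
  out
}

#' Exclude individuals with too many missing loci
#'
#' Individuals whose genotypes are missing at \code{max_missing} or more
#' loci are considered of poor DNA quality and removed.
#'
#' @param genotypes genotype matrix.
#' @param max_missing exclusion threshold (default 5 loci).
#' @return List with \code{genotypes} (retained rows), \code{removed}
#'   (character vector of excluded ids) and \code{n_missing} (per-individual
#'   counts on the input).
#' @export
filter_missing <- function(genotypes, max_missing = 5) {
  nm <- missing_loci(genotypes)
  drop <- nm >= max_missing
  list(genotypes = genotypes[!drop, , drop = FALSE],
       removed = rownames(genotypes)[drop],
       n_missing = nm)
}

#' Find duplicate genotypes
#'
#' Flags all pairs of individuals whose genotypes agree at every compared
#' locus, allowing up to \code{max_mismatch} mismatching loci; loci missing
#' in either member are skipped. Such duplicates typically indicate tag loss
#' and repeated sampling of one animal. Output order is deterministic
#' (lexicographic in the two ids) and invariant to input order.
#'
#' @param genotypes genotype matrix (>= 2 rows).
#' @param max_mismatch maximum number of mismatching loci tolerated
#'   (default 0 = exact identity on compared loci).
#' @param min_compared minimum number of loci compared for a pair to be
#'   eligible (guards against matches driven by missingness).
#' @return data.frame with \code{id1}, \code{id2}, \code{mismatches},
#'   \code{compared}.
#' @export
find_duplicates <- function(genotypes, max_mismatch = 0, min_compared = 5) {
  n <- nrow(genotypes)
  if (n < 2) stop("at least two individuals are required")
  L <- ncol(genotypes) / 2
  # canonical ordered-pair encoding per locus so A/B == B/A
  lo <- hi <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    a <- genotypes[, locus_cols(l), drop = FALSE]
    lo[, l] <- pmin(a[, 1], a[, 2])
    hi[, l] <- pmax(a[, 1], a[, 2])
  }
  ids <- rownames(genotypes)
  res <- list()
  # one-vs-rest comparison keeps this O(n^2 L) fully vectorized
  for (i in seq_len(n - 1)) {
    rows <- (i + 1):n
    li <- lo[rep(i, length(rows)), , drop = FALSE]
    hi_i <- hi[rep(i, length(rows)), , drop = FALSE]
    lj <- lo[rows, , drop = FALSE]
    hj <- hi[rows, , drop = FALSE]
    ok <- !is.na(li) & !is.na(lj)
    compared <- rowSums(ok)
    mm <- rowSums(ok & (li != lj | hi_i != hj), na.rm = TRUE)
    hit <- which(compared >= min_compared & mm <= max_mismatch)
    for (h in hit) {
      pair <- sort(c(ids[i], ids[rows[h]]))
      res[[length(res) + 1L]] <- data.frame(
        id1 = pair[1], id2 = pair[2], mismatches = mm[h],
        compared = compared[h], stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(id1 = character(0), id2 = character(0),
                      mismatches = integer(0), compared = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$id1, out$id2), , drop = FALSE]
}

#' Resolve duplicate pairs
#'
#' For each duplicate pair, keeps the record with fewer missing loci,
#' breaking ties by later capture year (the fresher sample).
#'
#' @param duplicates output of [find_duplicates()].
#' @param genotypes genotype matrix.
#' @param individuals individual table with \code{id} and \code{year}.
#' @return Character vector of ids to drop.
#' @export
resolve_duplicates <- function(duplicates, genotypes, individuals) {
  if (!nrow(duplicates)) return(character(0))
  nm <- missing_loci(genotypes)
  year <- individuals$year[match(names(nm), individuals$id)]
  drop <- character(0)
  for (r in seq_len(nrow(duplicates))) {
    a <- duplicates$id1[r]; b <- duplicates$id2[r]
    pick_b <- nm[a] > nm[b] ||
      (nm[a] == nm[b] && !is.na(year[match(a, names(nm))]) &&
         !is.na(year[match(b, names(nm))]) &&
         year[match(a, names(nm))] < year[match(b, names(nm))])
    drop <- c(drop, if (pick_b) a else b)
  }
  unique(drop)
}
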