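#' Write a genotype table to a GENEPOP file
#'
#' Writes the 3-digit allele dialect ("000" = missing, so a missing
#' genotype is "000000"). Population samples become POP blocks in order of
#' first appearance; individual ids are written verbatim before the comma.
#' Family and true-origin labels, which GENEPOP cannot carry, go to a
#' tab-separated sidecar file (`<path>.meta.tsv` by default) with columns
#' `individual_id`, `population`, `family_id`, `true_origin`;
#' [read_genepop()] picks it up automatically.
#'
#' @param gt A genotype table.
#' @param path Output file path.
#' @param title Title line for the file.
#' @param sidecar Write the metadata sidecar (default TRUE), or a path.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gt, path, title = "gsifam genotypes",
                          sidecar = TRUE) {
  w <- gt_wide(gt)
  fmt <- function(m1, m2) {
    g <- sprintf("%03d%03d", m1, m2)
    g[is.na(m1)] <- "000000"
    g
  }
  lines <- c(title, w$loci)
  for (p in unique(w$pop)) {
    lines <- c(lines, "POP")
    rows <- which(w$pop == p)
    geno <- vapply(rows, function(i) {
      paste(fmt(w$A1[i, ], w$A2[i, ]), collapse = " ")
    }, character(1))
    lines <- c(lines, paste0(w$ind[rows], " ,  ", geno))
  }
  writeLines(lines, path)
  if (!identical(sidecar, FALSE)) {
    sc <- if (is.character(sidecar)) sidecar else paste0(path, ".meta.tsv")
    meta <- gt_individuals(gt)
    names(meta) <- c("individual_id", "population", "family_id", "true_origin")
    utils::write.table(meta, sc, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  }
  invisible(path)
}

#' Read a GENEPOP file into a genotype table
#'
#' Accepts the 2- and 3-digit allele dialects (auto-detected from genotype
#' string width; "00"/"000" = missing). POP blocks become population
#' samples named `pop_1`, `pop_2`, ... unless a metadata sidecar written
#' by [write_genepop()] is found (or given), in which case population,
#' family and true-origin labels are restored from it. Without a sidecar,
#' each individual is its own family. Parse errors report the offending
#' line number.
#'
#' @param path Path to a GENEPOP file.
#' @param sidecar Path to a metadata sidecar TSV, TRUE to auto-detect
#'   `<path>.meta.tsv` (default), or FALSE to ignore.
#' @return A genotype table.
#' @export
read_genepop <- function(path, sidecar = TRUE) {
  lines <- readLines(path)
  if (length(lines) < 3) abort("not a GENEPOP file: fewer than 3 lines")
  lines <- sub("\\s+$", "", lines)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3) {
    abort("not a GENEPOP file: no POP line after the locus list")
  }
  header <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  pop_id <- cumsum(is_pop)
  recs <- which(!is_pop & seq_along(lines) >= first_pop & nzchar(trimws(lines)))
  parse_rec <- function(i) {
    ln <- lines[i]
    comma <- regexpr(",", ln, fixed = TRUE)
    if (comma < 0) {
      abort(paste0("line ", i, ": expected 'id , genotypes'"))
    }
    id <- trimws(substr(ln, 1, comma - 1))
    fields <- strsplit(trimws(substr(ln, comma + 1, nchar(ln))), "\\s+")[[1]]
    if (length(fields) != L) {
      abort(paste0("line ", i, ": ", length(fields),
                   " genotype field(s), expected ", L))
    }
    wdt <- unique(nchar(fields))
    if (length(wdt) != 1 || !wdt %in% c(4L, 6L)) {
      abort(paste0("line ", i,
                   ": genotype strings must be uniformly 4 or 6 digits"))
    }
    half <- wdt / 2
    a1 <- as.integer(substr(fields, 1, half))
    a2 <- as.integer(substr(fields, half + 1, wdt))
    if (any(is.na(a1)) || any(is.na(a2))) {
      abort(paste0("line ", i, ": non-numeric allele code"))
    }
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    bad <- xor(is.na(a1), is.na(a2))
    if (any(bad)) {
      abort(paste0("line ", i, ": half-missing genotype"))
    }
    list(id = id, pop = pop_id[i], a1 = a1, a2 = a2)
  }
  parsed <- lapply(recs, parse_rec)
  n <- length(parsed)
  if (n == 0) abort("no individual records found")
  A1 <- do.call(rbind, lapply(parsed, `[[`, "a1"))
  A2 <- do.call(rbind, lapply(parsed, `[[`, "a2"))
  ids <- vapply(parsed, `[[`, character(1), "id")
  popn <- sprintf("pop_%d", vapply(parsed, `[[`, numeric(1), "pop"))
  w <- list(ind = ids, pop = popn, family = ids,
            origin = rep(NA_character_, n), loci = loci, A1 = A1, A2 = A2,
            n_alleles = setNames(pmax(
              apply(A1, 2, function(v) max(v, 0L, na.rm = TRUE)),
              apply(A2, 2, function(v) max(v, 0L, na.rm = TRUE)), 1L), loci))
  gt <- gt_from_wide(w)
  sc <- NULL
  if (is.character(sidecar)) {
    sc <- sidecar
  } else if (isTRUE(sidecar) && file.exists(paste0(path, ".meta.tsv"))) {
    sc <- paste0(path, ".meta.tsv")
  }
  if (!is.null(sc)) {
    meta <- utils::read.table(sc, header = TRUE, sep = "\t",
                              colClasses = "character", na.strings = "")
    m <- match(gt$individual, meta$individual_id)
    if (any(is.na(m))) {
      warn("sidecar does not cover every individual; labels kept as parsed")
    } else {
      gt$pop <- meta$population[m]
      gt$family <- meta$family_id[m]
      gt$origin <- meta$true_origin[m]
    }
  }
  genotype_table(gt, n_alleles = attr(gt, "n_alleles"))
}

#' Genotype completeness summary
#'
#' Tallies individuals by their number of missing single-locus genotypes
#' and reports the overall percentage of missing genotype calls (two
#' decimals) and the percentage of individuals with complete multilocus
#' genotypes (one decimal).
#'
#' @param gt A genotype table.
#' @return Object of class `qc_summary` with fields `n_individuals`,
#'   `n_loci`, `missing_by_individual` (tibble: `n_missing_loci`,
#'   `n_individuals`), `pct_missing_calls`, `pct_complete`. `glance()`
#'   returns the scalars as a one-row tibble.
#' @export
qc_completeness <- function(gt) {
  if (nrow(gt) == 0) abort("empty genotype table")
  w <- gt_wide(gt)
  n <- length(w$ind)
  L <- length(w$loci)
  miss <- rowSums(is.na(w$A1))
  tab <- tibble::tibble(n_missing_loci = sort(unique(miss))) |>
    dplyr::mutate(n_individuals = vapply(.data$n_missing_loci,
                                         function(m) sum(miss == m),
                                         numeric(1)))
  structure(list(
    n_individuals = n,
    n_loci = L,
    missing_by_individual = tab,
    pct_missing_calls = round(100 * sum(miss) / (n * L), 2),
    pct_complete = round(100 * sum(miss == 0) / n, 1)
  ), class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(x$n_individuals, "individuals x", x$n_loci, "loci:",
      paste0(format(x$pct_missing_calls, nsmall = 2), "% missing calls, "),
      paste0(format(x$pct_complete, nsmall = 1),
             "% individuals with complete genotypes\n"))
  invisible(x)
}

#' One-row QC summary
#'
#' @param x A `qc_summary` object.
#' @param ... Unused.
#' @return Tibble with `n_individuals`, `n_loci`, `pct_missing_calls`,
#'   `pct_complete`.
#' @method glance qc_summary
#' @export
glance.qc_summary <- function(x, ...) {
  tibble::tibble(n_individuals = x$n_individuals, n_loci = x$n_loci,
                 pct_missing_calls = x$pct_missing_calls,
                 pct_complete = x$pct_complete)
}
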