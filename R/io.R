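#' @rdname table_io
#' @details Count tables are strand-specific allele counts with columns
#' `sample`, `chrom`, `pos` (1-based), `ref`, `strand` ("fwd"/"rev"), `A`,
#' `C`, `G`, `T`, `DEL`, `depth`. Clone tables have `clone_id` and `cells`
#' and/or `vaf`. Mutation tables have `sample`, `chrom`, `pos`, `ref`, `alt`,
#' `vaf`, `consequence` (one of synonymous, nonsynonymous, frameshift,
#' splicing, other) and optionally `context`.
#' @export
read_counts <- function(path) {
  tab <- read_checked(path, readr::cols(
    sample = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), ref = readr::col_character(),
    strand = readr::col_character(), A = readr::col_integer(),
    C = readr::col_integer(), G = readr::col_integer(),
    T = readr::col_integer(), DEL = readr::col_integer(),
    depth = readr::col_integer()))
  check_count_table(tab)
  tab
}

#' Read and write the package's tab-separated tables
#'
#' Lossless TSV round-trips for the count, clone, mutation and call tables.
#' Malformed rows raise an error naming the offending line.
#'
#' @param path File path.
#' @param x Table to write.
#' @name table_io
#' @return A tibble (readers) or `path`, invisibly (writers).
#' @export
read_clone_table <- function(path) {
  tab <- read_checked(path, readr::cols())
  if (!"clone_id" %in% names(tab) || !any(c("cells", "vaf") %in% names(tab)))
    abort(sprintf("%s: clone tables need columns clone_id and cells or vaf", path))
  tab
}

#' @rdname table_io
#' @export
read_mutation_table <- function(path) {
  tab <- read_checked(path, readr::cols())
  need <- c("sample", "chrom", "pos", "ref", "alt", "vaf")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    abort(sprintf("%s: missing mutation-table columns: %s", path,
                  paste(miss, collapse = ", ")))
  if (any(tab$vaf <= 0 | tab$vaf > 1)) abort("vaf must lie in (0, 1]")
  tab
}

#' @rdname table_io
#' @export
write_table <- function(x, path) {
  x <- dplyr::select(as_tibble(x), -dplyr::any_of("merged_from"))
  readr::write_tsv(x, path)
  invisible(path)
}

read_checked <- function(path, col_types) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  tab <- suppressWarnings(readr::read_tsv(path, col_types = col_types,
                                          show_col_types = FALSE,
                                          progress = FALSE))
  pr <- readr::problems(tab)
  if (nrow(pr) > 0)
    abort(sprintf("%s: malformed row at line %d (expected %s)", path, pr$row[1],
                  pr$expected[1]))
  tab
}

check_count_table <- function(tab) {
  need <- c("sample", "chrom", "pos", "ref", "strand", "A", "C", "G", "T",
            "DEL", "depth")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    abort(sprintf("missing count-table columns: %s", paste(miss, collapse = ", ")))
  if (!all(tab$strand %in% c("fwd", "rev")))
    abort("strand must be 'fwd' or 'rev'")
  cnt <- as.matrix(tab[, c("A", "C", "G", "T", "DEL")])
  if (any(cnt < 0)) abort("negative allele counts")
  if (any(rowSums(cnt) > tab$depth)) abort("allele counts exceed coverage")
  invisible(tab)
}

# long format: one row per sample/site/strand/allele
counts_to_long <- function(tab) {
  tab |>
    tidyr::pivot_longer(cols = c("A", "C", "G", "T", "DEL"),
                        names_to = "allele", values_to = "count") |>
    dplyr::mutate(allele = ifelse(.data$allele == "DEL", "-", .data$allele),
                  ref = .data$ref)
}

#' Read capture-target intervals from BED
#'
#' BED uses 0-based half-open intervals; the returned tibble carries both the
#' raw BED coordinates and the 1-based inclusive positions they cover (an
#' interval `(start = 10, end = 20)` covers 1-based positions 11 to 20).
#'
#' @param path BED file path.
#' @return A tibble with `chrom`, `start0`, `end0`, `pos_first`, `pos_last`.
#' @export
read_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    abort("read_bed() needs the rtracklayer package")
  gr <- rtracklayer::import(path, format = "BED")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start0 = GenomicRanges::start(gr) - 1L,
         end0 = GenomicRanges::end(gr),
         pos_first = GenomicRanges::start(gr),
         pos_last = GenomicRanges::end(gr))
}

#' Write variant calls as minimal VCF 4.2
#'
#' One record per call; merged complex events are written with the symbolic
#' `<DEL>` allele and an END tag. INFO carries VAF, SUPPORT and QVAL.
#'
#' @param calls A `variant_calls` tibble from [call_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=clonedrift-%s",
                   as.character(utils::packageVersion("clonedrift"))),
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
           "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
           "##INFO=<ID=QVAL,Number=1,Type=Float,Description=\"BH-adjusted p-value\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of merged deletion\">",
           "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample of origin\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  rows <- vapply(seq_len(nrow(calls)), function(i) {
    r <- calls[i, ]
    alt <- if (r$alt == "-") "<DEL>" else r$alt
    info <- sprintf("VAF=%.6g;SUPPORT=%d;QVAL=%.6g;SAMPLE=%s",
                    r$vaf, as.integer(r$support), r$q_value, r$sample)
    if (r$end > r$pos) info <- sprintf("%s;END=%d", info, as.integer(r$end))
    paste(r$chrom, r$pos, ".", r$ref, alt, ".", "PASS", info, sep = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Substitution-spectrum summary of a mutation table
#'
#' Tabulates base substitutions by the 12 directional classes, the 6
#' pyrimidine-collapsed classes (C>A, C>G, C>T, T>A, T>C, T>G, counting each
#' substitution by its pyrimidine-strand representation), and, when
#' trinucleotide contexts are present, the 96 context classes. Totals over
#' classes equal the number of substitution rows.
#'
#' @param mutations Mutation table with `ref` and `alt` single-base columns
#'   and optionally `context` (trinucleotide, middle base = ref).
#' @return A list with tibbles `by_class`, `by_class6` and (if contexts are
#'   available) `by_context`.
#' @export
spectrum_summary <- function(mutations) {
  bases <- c("A", "C", "G", "T")
  snv <- mutations[mutations$ref %in% bases & mutations$alt %in% bases &
                     mutations$ref != mutations$alt, ]
  bad <- mutations[!mutations$ref %in% c(bases, "-") |
                     !(mutations$alt %in% bases | mutations$alt %in% c("-", "<DEL>")), ]
  if (nrow(bad) > 0)
    abort(sprintf("unknown base characters in mutation table: %s>%s",
                  bad$ref[1], bad$alt[1]))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cls12 <- paste0(snv$ref, ">", snv$alt)
  pyr <- snv$ref %in% c("C", "T")
  cls6 <- ifelse(pyr, cls12, paste0(comp[snv$ref], ">", comp[snv$alt]))
  all12 <- paste0(rep(bases, each = 3), ">",
                  unlist(lapply(bases, function(b) setdiff(bases, b))))
  by_class <- tibble(class = all12,
                     count = as.integer(table(factor(cls12, levels = all12))))
  all6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  by_class6 <- tibble(class = all6,
                      count = as.integer(table(factor(cls6, levels = all6))))
  out <- list(by_class = by_class, by_class6 = by_class6)
  if ("context" %in% names(snv) && all(!is.na(snv$context))) {
    ctx <- snv$context
    rc <- function(s) chartr("ACGT", "TGCA", vapply(strsplit(s, ""), function(x)
      paste(rev(x), collapse = ""), character(1)))
    ctx_pyr <- ifelse(pyr, ctx, rc(ctx))
    key <- paste0(substr(ctx_pyr, 1, 1), "[", cls6, "]", substr(ctx_pyr, 3, 3))
    all96 <- unlist(lapply(all6, function(c6)
      paste0(rep(bases, each = 4), "[", c6, "]", rep(bases, times = 4))))
    out$by_context <- tibble(context = sort(all96),
                             count = as.integer(table(factor(key, levels = sort(all96)))))
  }
  out
}

#' Clone-size distributions stratified by mutation consequence
#'
#' Splits a mutation table into a synonymous (neutral) stratum and a
#' protein-altering stratum (nonsynonymous, frameshift, splicing) and
#' computes the empirical first incomplete moment of the VAF distribution in
#' each; an excess of large clones in the protein-altering stratum shows up
#' as a heavier tail above the neutral curve.
#'
#' @param mutations Mutation table with `vaf` and `consequence` columns.
#' @return A tibble with one row per non-empty stratum: `stratum`, `n`,
#'   `sizes` (list), `curve` (list of incomplete-moment tibbles). Empty
#'   strata are flagged with a message and skipped.
#' @export
stratified_distributions <- function(mutations) {
  stopifnot(all(c("vaf", "consequence") %in% names(mutations)))
  strata <- list(
    synonymous = mutations$consequence == "synonymous",
    protein_altering = mutations$consequence %in%
      c("nonsynonymous", "frameshift", "splicing"))
  rows <- purrr::imap(strata, function(idx, name) {
    v <- mutations$vaf[idx]
    if (length(v) == 0) {
      message(sprintf("stratum '%s' is empty; skipped", name))
      return(NULL)
    }
    tibble(stratum = name, n = length(v), sizes = list(v),
           curve = list(first_incomplete_moment(v)))
  })
  purrr::list_rbind(purrr::compact(rows))
}
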