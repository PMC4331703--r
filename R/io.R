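#' Read and write base-count tables
#'
#' The on-disk format is a TSV with header `sample  site  A  C  G  T`, one
#' row per (sample, site) pair. Reading preserves first-appearance sample
#' order and sorts sites by ascending position; a written file read back
#' yields the identical table.
#'
#' @param path file path.
#' @return `read_counts_tsv()` returns a base-count tibble;
#'   `write_counts_tsv()` returns `path` invisibly.
#' @export
read_counts_tsv <- function(path) {
  df <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(), site = readr::col_integer(),
    A = readr::col_integer(), C = readr::col_integer(),
    G = readr::col_integer(), T = readr::col_integer()
  )))
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(sprintf("malformed count row at line %d: %s", prob$row[1] + 1L, prob$expected[1]))
  }
  cm <- as.matrix(df[, CNV_BASES])
  if (anyNA(cm) || any(cm < 0)) {
    bad <- which(rowSums(is.na(cm) | cm < 0) > 0)[1]
    abort(sprintf("negative or missing count at line %d", bad + 1L))
  }
  dup <- which(duplicated(df[, c("sample", "site")]))
  if (length(dup) > 0) {
    abort(sprintf("duplicate (sample, site) pair at line %d", dup[1] + 1L))
  }
  df |>
    dplyr::mutate(sample = factor(.data$sample, levels = unique(.data$sample))) |>
    dplyr::arrange(.data$sample, .data$site) |>
    dplyr::mutate(sample = as.character(.data$sample))
}

#' @rdname read_counts_tsv
#' @param counts base-count tibble (see [count_tbl()]).
#' @export
write_counts_tsv <- function(counts, path) {
  validate_counts(counts)
  out <- counts |>
    dplyr::mutate(sample = factor(.data$sample, levels = unique(.data$sample))) |>
    dplyr::arrange(.data$sample, .data$site) |>
    dplyr::mutate(sample = as.character(.data$sample))
  readr::write_tsv(out[, c("sample", "site", CNV_BASES)], path)
  invisible(path)
}

# Parse one mpileup read-bases string against its reference base, returning
# counts of A/C/G/T and deletions. Handles . , (ref match), ACGTacgt,
# ^X (read start; the mapping-quality character is skipped), $ (read end),
# +N/-N followed by N inserted/deleted bases (skipped), * (deletion on this
# row), and > < N n (reference skips / unknown, ignored). Case is folded:
# the model has no strand term.
parse_bases_field <- function(bases, ref) {
  counts <- setNames(numeric(5), c(CNV_BASES, "del"))
  chars <- strsplit(bases, "")[[1]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L
    } else if (ch == "$" || ch %in% c(">", "<", "N", "n")) {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
    } else if (ch == "." || ch == ",") {
      counts[ref] <- counts[ref] + 1
      i <- i + 1L
    } else if (toupper(ch) %in% CNV_BASES) {
      counts[toupper(ch)] <- counts[toupper(ch)] + 1
      i <- i + 1L
    } else if (ch == "*" || ch == "#") {
      counts["del"] <- counts["del"] + 1
      i <- i + 1L
    } else {
      abort(sprintf("unrecognised pileup symbol '%s'", ch))
    }
  }
  counts
}

#' Parse samtools-mpileup text into per-sample base counts
#'
#' Reads multi-sample mpileup lines (`chrom pos ref` followed by a
#' depth/bases/qualities column triple per sample) and tallies A/C/G/T and
#' deletion counts per sample and position.
#'
#' @param lines character vector of mpileup lines (or a file read with
#'   `readLines()`).
#' @param sample_ids sample identifiers, one per column triple.
#'
#' @return A tibble with columns `sample`, `chrom`, `pos`, `ref`, `A`, `C`,
#'   `G`, `T`, `del`.
#' @export
parse_pileup <- function(lines, sample_ids) {
  lines <- lines[nzchar(lines)]
  purrr::imap_dfr(lines, function(line, li) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 3 + 3 * length(sample_ids)) {
      abort(sprintf(
        "pileup line %d has %d fields; expected %d for %d samples",
        li, length(f), 3 + 3 * length(sample_ids), length(sample_ids)
      ))
    }
    ref <- toupper(f[3])
    purrr::map_dfr(seq_along(sample_ids), function(s) {
      cnt <- parse_bases_field(f[3 * s + 2], ref)
      tibble::tibble(
        sample = sample_ids[s], chrom = f[1], pos = as.integer(f[2]), ref = ref,
        A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
        del = cnt[["del"]]
      )
    })
  })
}

#' Identify variable sites from raw per-site counts
#'
#' A site passes the minor-base filter if, in at least one sample, the count
#' of that sample's second-most-frequent nucleotide is at least `minor_min`.
#' The deletion ratio is pooled over samples,
#' `deletions / (deletions + all bases)`, and a site is omitted when the
#' ratio reaches `del_ratio_max` (inclusive boundary). A site is kept iff it
#' passes the minor filter and survives the deletion filter. Raising
#' `minor_min` never adds a kept site; raising `del_ratio_max` never removes
#' one.
#'
#' @param raw tibble from [parse_pileup()] (columns `sample`, `pos`, `A`,
#'   `C`, `G`, `T`, `del`).
#' @param minor_min minimum per-sample minor-base count.
#' @param del_ratio_max pooled deletion-ratio threshold (sites at or above
#'   it are dropped).
#'
#' @return A tibble with one row per position: `pos`,
#'   `passes_minor_filter`, `deletion_ratio`, `kept`.
#' @export
identify_variable_sites <- function(raw, minor_min = 15, del_ratio_max = 0.1) {
  if (nrow(raw) == 0) abort("raw site counts are empty")
  minor2 <- function(a, c, g, t) {
    vapply(seq_along(a), function(i) {
      sort(c(a[i], c[i], g[i], t[i]), decreasing = TRUE)[2]
    }, numeric(1))
  }
  raw |>
    dplyr::group_by(.data$pos) |>
    dplyr::summarise(
      passes_minor_filter = any(minor2(.data$A, .data$C, .data$G, .data$T) >= minor_min),
      deletion_ratio = {
        tot <- sum(.data$del) + sum(.data$A + .data$C + .data$G + .data$T)
        if (tot == 0) 0 else sum(.data$del) / tot
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(kept = .data$passes_minor_filter &
                    .data$deletion_ratio < del_ratio_max) |>
    dplyr::arrange(.data$pos)
}

#' Base-count table restricted to kept variable sites
#'
#' Projects raw per-site counts onto the sites kept by
#' [identify_variable_sites()], dropping the deletion column (deletion
#' filtering is site-level: a kept site contributes only its A/C/G/T
#' counts).
#'
#' @param raw tibble from [parse_pileup()].
#' @param site_table tibble from [identify_variable_sites()].
#' @return A base-count tibble with `site` set to the genomic position.
#' @export
variable_site_counts <- function(raw, site_table) {
  keep <- site_table$pos[site_table$kept]
  raw |>
    dplyr::filter(.data$pos %in% keep) |>
    dplyr::transmute(.data$sample, site = .data$pos,
                     .data$A, .data$C, .data$G, .data$T)
}

#' Read and write allele sets as FASTA
#'
#' One record per allele; the header is the allele label. On read, lowercase
#' bases are upcased with a warning and any non-ACGT character is an error.
#'
#' @param path file path.
#' @param alleles allele tibble with columns `label` and `sequence`.
#' @return `read_alleles_fasta()` returns an allele tibble;
#'   `write_alleles_fasta()` returns `path` invisibly.
#' @export
read_alleles_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  if (any(grepl("[acgt]", seqs))) {
    warn("lowercase bases in FASTA; upcasing")
    seqs <- toupper(seqs)
  }
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    abort(sprintf("non-ACGT character in FASTA record '%s'", names(ss)[bad][1]))
  }
  tibble::tibble(label = names(ss), sequence = unname(seqs))
}

#' @rdname read_alleles_fasta
#' @export
write_alleles_fasta <- function(alleles, path) {
  stopifnot(all(c("label", "sequence") %in% names(alleles)))
  ss <- Biostrings::DNAStringSet(setNames(alleles$sequence, alleles$label))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
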