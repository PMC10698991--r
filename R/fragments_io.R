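#' Write fragments to disk
#'
#' Two formats are supported. `"tsv"` writes the documented fragment table
#' (columns `sample_id`, `amplicon_id`, `fragment_id`, `cpg_calls` — one
#' character per scored CpG over \{M,U,.\}, ordered by CpG index —, and
#' `snp_base`), which round-trips losslessly through [read_alignments()].
#' `"sam"` writes a spec-valid SAM file in bisulfite base space: each
#' fragment becomes a concordant mate pair over the amplicon interval, with
#' methylated CpG cytosines as `C`, unmethylated as `T`, missing calls as
#' `N`, and the SNP base substituted at the SNP locus. When a `true_clone`
#' column is present, it is carried as an optional `ZT` tag for debugging.
#'
#' @param fragments Fragment tibble (as produced by [simulate_sample()]).
#' @param path Output file path.
#' @param format `"tsv"` or `"sam"`.
#' @param map A [promoter_map()]; required for SAM output.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path, format = c("tsv", "sam"),
                            map = NULL) {
  if (!is.character(format) || !all(format %in% c("tsv", "sam"))) {
    stop("unknown fragment format; use \"tsv\" or \"sam\"", call. = FALSE)
  }
  format <- match.arg(format)
  cols <- c("sample_id", "amplicon_id", "fragment_id", "cpg_calls", "snp_base")
  if (!all(cols %in% names(fragments))) {
    stop("fragments need columns: ", paste(cols, collapse = ", "), call. = FALSE)
  }
  if (format == "tsv") {
    readr::write_tsv(fragments[cols], path)
  } else {
    if (is.null(map)) stop("SAM output needs `map`", call. = FALSE)
    writeLines(fragments_to_sam(fragments, map), path)
  }
  invisible(path)
}

# reference bases for a genomic window: 'A' background, CpGs as C/G,
# SNP ref base at the SNP locus (synthetic sequence, no off-target cytosines)
window_reference <- function(map, start, end) {
  chars <- rep("A", end - start + 1L)
  cp <- map$cpgs$pos
  in_c <- cp >= start & cp <= end
  chars[cp[in_c] - start + 1L] <- "C"
  in_g <- (cp + 1L) >= start & (cp + 1L) <= end
  chars[cp[in_g] + 1L - start + 1L] <- "G"
  if (map$snp$position >= start && map$snp$position <= end) {
    chars[map$snp$position - start + 1L] <- map$snp$ref_base
  }
  chars
}

# read sequence for [start, end]: reference with CpG cytosines set from the
# fragment's calls and the SNP base substituted
fragment_window_seq <- function(map, amp, start, end, calls_chars, snp_base) {
  chars <- window_reference(map, start, end)
  idx <- seq(amp$cpg_lo, amp$cpg_hi)
  pos <- map$cpgs$pos[idx + 1L]
  keep <- pos >= start & pos <= end
  base <- c(M = "C", U = "T", "." = "N")[calls_chars[keep]]
  chars[pos[keep] - start + 1L] <- unname(base)
  if (!is.na(snp_base) && snp_base != "." &&
      map$snp$position >= start && map$snp$position <= end) {
    chars[map$snp$position - start + 1L] <- snp_base
  }
  paste(chars, collapse = "")
}

fragments_to_sam <- function(fragments, map) {
  ln <- max(map$amplicons$end) + 1000L
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", map$contig, ln),
              "@PG\tID:epivef\tPN:epivef")
  has_truth <- "true_clone" %in% names(fragments)
  recs <- purrr::map(split(fragments, fragments$amplicon_id), function(fr) {
    amp <- map$amplicons[map$amplicons$amplicon_id == fr$amplicon_id[1L], ]
    alen <- amp$end - amp$start + 1L
    rl <- min(226L, alen)
    s1 <- amp$start; e1 <- amp$start + rl - 1L
    s2 <- amp$end - rl + 1L; e2 <- amp$end
    qual <- strrep("I", rl)
    call_mat <- strsplit(fr$cpg_calls, "", fixed = TRUE)
    purrr::map_chr(seq_len(nrow(fr)), function(i) {
      seq1 <- fragment_window_seq(map, amp, s1, e1, call_mat[[i]], fr$snp_base[i])
      seq2 <- fragment_window_seq(map, amp, s2, e2, call_mat[[i]], fr$snp_base[i])
      tag <- if (has_truth) {
        sprintf("\tZT:Z:%s", if (isTRUE(fr$true_clone[i])) "clone" else "background")
      } else ""
      paste0(
        sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s%s",
                fr$fragment_id[i], map$contig, s1, rl, s2, alen, seq1, qual, tag),
        "\n",
        sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s%s",
                fr$fragment_id[i], map$contig, s2, rl, s1, -alen, seq2, qual, tag)
      )
    })
  })
  c(header, unlist(recs, use.names = FALSE))
}

#' Read aligned bisulfite fragments
#'
#' Ingests either the fragment TSV written by [write_fragments()] or a
#' SAM/BAM file of paired, ungapped amplicon alignments. For SAM/BAM, mate
#' pairs are merged into fragments: at each scored CpG cytosine a `C` is
#' called methylated, a `T` unmethylated, and any other base — or mates
#' disagreeing at that CpG — yields a missing call (`.`). The SNP base is
#' extracted where covered, with mate disagreement again giving `.`.
#' Unmapped reads are dropped (an all-unmapped file yields an empty set
#' with a warning); reads on an unexpected contig or with non-simple CIGAR
#' are skipped and counted in a message.
#'
#' @param path Input file (`.tsv`, `.sam` or `.bam`).
#' @param map A [promoter_map()].
#' @param sample_id Sample identifier for SAM/BAM input (the format does
#'   not carry one); defaults to the file name without extension.
#' @return Fragment tibble with columns `sample_id`, `amplicon_id`,
#'   `fragment_id`, `cpg_calls`, `snp_base`.
#' @export
read_alignments <- function(path, map, sample_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "tsv") {
    fr <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
    need <- c("sample_id", "amplicon_id", "fragment_id", "cpg_calls", "snp_base")
    if (!all(need %in% names(fr))) {
      stop("fragment TSV is missing columns: ",
           paste(setdiff(need, names(fr)), collapse = ", "), call. = FALSE)
    }
    return(fr[need])
  }
  if (!ext %in% c("sam", "bam")) {
    stop("unknown alignment format: .", ext, call. = FALSE)
  }
  sample_id <- sample_id %||% sub("\\.(sam|bam)$", "", basename(path),
                                  ignore.case = TRUE)
  bam <- if (ext == "sam") {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else {
    path
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar", "seq")
    )
  )[[1L]]
  n_all <- length(res$qname)
  mapped <- !bitwAnd(res$flag, 4L)
  if (!any(mapped)) {
    warning("no mapped reads in ", path, call. = FALSE)
    return(tibble::tibble(sample_id = character(), amplicon_id = character(),
                          fragment_id = character(), cpg_calls = character(),
                          snp_base = character()))
  }
  on_contig <- mapped & as.character(res$rname) == map$contig
  simple <- grepl("^\\d+M$", res$cigar)
  keep <- which(on_contig & simple)
  n_skip <- sum(mapped) - length(keep)
  if (n_skip > 0) {
    message(n_skip, " mapped read(s) skipped (unexpected contig or CIGAR)")
  }

  qname <- res$qname[keep]
  pos <- res$pos[keep]
  width <- as.integer(sub("M$", "", res$cigar[keep]))
  seqs <- as.character(res$seq[keep])
  amp_tbl <- map$amplicons

  # fragment span -> amplicon assignment (smallest amplicon containing it)
  span <- tibble::tibble(qname = qname, lo = pos, hi = pos + width - 1L) |>
    dplyr::group_by(.data$qname) |>
    dplyr::summarise(lo = min(.data$lo), hi = max(.data$hi), .groups = "drop")
  assign_amp <- function(lo, hi) {
    hit <- which(amp_tbl$start <= lo & amp_tbl$end >= hi)
    if (length(hit) == 0L) return(NA_character_)
    amp_tbl$amplicon_id[hit[which.min(amp_tbl$end[hit] - amp_tbl$start[hit])]]
  }
  span$amplicon_id <- purrr::map2_chr(span$lo, span$hi, assign_amp)
  n_unassigned <- sum(is.na(span$amplicon_id))
  if (n_unassigned > 0) {
    message(n_unassigned, " fragment(s) not contained in any amplicon; skipped")
    span <- span[!is.na(span$amplicon_id), ]
  }
  frag_amp <- stats::setNames(span$amplicon_id, span$qname)
  read_amp <- unname(frag_amp[qname])
  ok_read <- !is.na(read_amp)

  # base at genomic position p, vectorised over reads; NA where not covered
  bases_at <- function(idx, p) {
    off <- p - pos[idx] + 1L
    cov <- off >= 1L & off <= width[idx]
    out <- rep(NA_character_, length(idx))
    if (any(cov)) {
      out[cov] <- substring(seqs[idx][cov], off[cov], off[cov])
    }
    out
  }
  merge_mates <- function(b1, b2) {
    ifelse(is.na(b1), b2,
           ifelse(is.na(b2), b1, ifelse(b1 == b2, b1, NA_character_)))
  }

  out <- purrr::map(unique(span$amplicon_id), function(aid) {
    idx <- which(ok_read & read_amp == aid)
    # first two mates per fragment, vectorised
    ord <- idx[order(qname[idx], pos[idx])]
    qn <- qname[ord]
    first <- !duplicated(qn)
    i1 <- ord[first]
    second_of <- match(unique(qn), qn[!first])
    i2 <- ord[!first][second_of]  # NA when a fragment has a single read
    amp <- amp_tbl[amp_tbl$amplicon_id == aid, ]
    cpg_pos <- map$cpgs$pos[seq(amp$cpg_lo, amp$cpg_hi) + 1L]
    nfr <- length(i1)
    callm <- matrix(".", nrow = nfr, ncol = length(cpg_pos))
    for (j in seq_along(cpg_pos)) {
      b1 <- bases_at(i1, cpg_pos[j])
      b2 <- rep(NA_character_, nfr)
      has2 <- !is.na(i2)
      if (any(has2)) b2[has2] <- bases_at(i2[has2], cpg_pos[j])
      b <- merge_mates(b1, b2)
      callm[, j] <- dplyr::case_when(is.na(b) ~ ".", b == "C" ~ "M",
                                     b == "T" ~ "U", TRUE ~ ".")
    }
    sb <- rep(".", nfr)
    if (map$snp$position >= amp$start && map$snp$position <= amp$end) {
      b1 <- bases_at(i1, map$snp$position)
      b2 <- rep(NA_character_, nfr)
      has2 <- !is.na(i2)
      if (any(has2)) b2[has2] <- bases_at(i2[has2], map$snp$position)
      b <- merge_mates(b1, b2)
      sb <- ifelse(is.na(b), ".", b)
    }
    tibble::tibble(
      sample_id = sample_id, amplicon_id = aid, fragment_id = qname[i1],
      cpg_calls = do.call(paste0, lapply(seq_len(ncol(callm)),
                                         function(j) callm[, j])),
      snp_base = sb
    )
  })
  dplyr::bind_rows(out) |> dplyr::arrange(.data$fragment_id)
}
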