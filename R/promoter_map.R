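#' Define the promoter region assayed by a bisulfite amplicon panel
#'
#' A promoter map is the coordinate system every other function in epivef
#' works in: the ordered CpG sites of the region (index, zero-padded label,
#' genomic coordinate), the amplicons of the panel with the contiguous CpG
#' index range each one scores, and the single biallelic SNP used to phase
#' epialleles to alleles. Coordinates may run in either genomic direction
#' (a minus-strand promoter has CpG indices increasing as coordinates
#' decrease) but must be strictly monotone.
#'
#' @param cpg_positions Integer vector of genomic coordinates (1-based) of
#'   the CpG cytosines, ordered by CpG index. Must be strictly monotone.
#' @param amplicons Data frame with columns `amplicon_id`, `cpg_lo`,
#'   `cpg_hi` (inclusive 0-based CpG indices), `start`, `end` (1-based
#'   inclusive genomic interval). Each amplicon scores exactly the CpGs
#'   `cpg_lo..cpg_hi`, all of which must fall inside its interval.
#' @param snp List with `position` (genomic coordinate), `ref_base`,
#'   `alt_base` (distinct single nucleotides) and `bisulfite_safe`
#'   (logical: both alleles remain distinguishable after C-to-T conversion
#'   on the sequenced strand). The SNP must lie inside at least one
#'   amplicon interval and must not coincide with a CpG cytosine.
#' @param region_id,contig,strand Identifiers carried through to outputs.
#'
#' @return An object of class `promoter_map`: a list with tibbles `cpgs`
#'   (`cpg_index`, `cpg_label`, `pos`) and `amplicons`, the `snp` list, and
#'   the identifiers.
#' @seealso [default_promoter_map()] for the bundled four-amplicon layout,
#'   [read_promoter_map()] for YAML input.
#' @export
#' @examples
#' map <- default_promoter_map()
#' map$amplicons
promoter_map <- function(cpg_positions, amplicons, snp,
                         region_id = "promoter", contig = "chr17",
                         strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  cpg_positions <- as.numeric(cpg_positions)
  n <- length(cpg_positions)
  if (n < 2L) stop("a promoter map needs at least two CpG sites", call. = FALSE)
  d <- diff(cpg_positions)
  if (!(all(d > 0) || all(d < 0))) {
    stop("CpG coordinates must be strictly monotone", call. = FALSE)
  }

  amplicons <- tibble::as_tibble(amplicons)
  need <- c("amplicon_id", "cpg_lo", "cpg_hi", "start", "end")
  if (!all(need %in% names(amplicons))) {
    stop("`amplicons` needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(amplicons) < 1L) stop("at least one amplicon is required", call. = FALSE)
  with(amplicons, {
    if (any(cpg_lo > cpg_hi)) stop("amplicon cpg_lo > cpg_hi", call. = FALSE)
    if (any(cpg_lo < 0L) || any(cpg_hi > n - 1L)) {
      stop("amplicon CpG range outside 0..", n - 1L, call. = FALSE)
    }
    if (any(cpg_lo != round(cpg_lo)) || any(cpg_hi != round(cpg_hi))) {
      stop("amplicon CpG indices must be integers (contiguous ranges only)",
           call. = FALSE)
    }
  })
  for (i in seq_len(nrow(amplicons))) {
    idx <- seq(amplicons$cpg_lo[i], amplicons$cpg_hi[i])
    pos <- cpg_positions[idx + 1L]
    if (any(pos < amplicons$start[i] | pos > amplicons$end[i])) {
      stop("amplicon ", amplicons$amplicon_id[i],
           ": scored CpGs fall outside its genomic interval", call. = FALSE)
    }
  }

  stopifnot(is.list(snp))
  for (f in c("position", "ref_base", "alt_base")) {
    if (is.null(snp[[f]])) stop("snp$", f, " is required", call. = FALSE)
  }
  if (is.null(snp$bisulfite_safe)) snp$bisulfite_safe <- TRUE
  if (identical(snp$ref_base, snp$alt_base)) {
    stop("SNP ref and alt bases must differ", call. = FALSE)
  }
  if (snp$position %in% cpg_positions) {
    stop("SNP position coincides with a CpG cytosine; ",
         "methylation and genotype signals would be confounded", call. = FALSE)
  }
  covering <- amplicons$amplicon_id[
    snp$position >= amplicons$start & snp$position <= amplicons$end
  ]
  if (length(covering) == 0L) {
    stop("SNP position is not covered by any amplicon", call. = FALSE)
  }
  snp$amplicon_id <- covering[[1L]]

  structure(
    list(
      region_id = region_id,
      contig = contig,
      strand = strand,
      cpgs = tibble::tibble(
        cpg_index = seq_len(n) - 1L,
        cpg_label = sprintf("CpG%02d", seq_len(n) - 1L),
        pos = cpg_positions
      ),
      amplicons = amplicons,
      snp = snp
    ),
    class = "promoter_map"
  )
}

#' The bundled four-amplicon promoter layout
#'
#' A synthetic stand-in for a BRCA1-promoter-style panel: 50 CpGs
#' (CpG00..CpG49) whose coordinates decrease with index (minus-strand
#' promoter), four overlapping amplicons scoring CpGs 0-13, 14-31, 17-34
#' and 33-49 with genomic intervals matching the assay this layout
#' emulates, and one bisulfite-safe A/G SNP inside the CpG33-49 amplicon.
#' The sequence context is synthetic; CpG counts, spacing and amplicon
#' intervals follow the panel design.
#'
#' @return A [promoter_map()].
#' @export
default_promoter_map <- function() {
  pos <- c(
    43126010 - 28 * (0:13),        # CpG00..CpG13
    c(43125600, 43125580, 43125562),  # CpG14..CpG16
    43125540 - 18 * (0:14),        # CpG17..CpG31
    43125260,                      # CpG32
    c(43125240, 43125210),         # CpG33..CpG34
    43125150 - 18 * (0:14)         # CpG35..CpG49
  )
  amps <- tibble::tibble(
    amplicon_id = c("CpG00-13", "CpG14-31", "CpG17-34", "CpG33-49"),
    cpg_lo = c(0L, 14L, 17L, 33L),
    cpg_hi = c(13L, 31L, 34L, 49L),
    start = c(43125624, 43125270, 43125171, 43124861),
    end   = c(43126026, 43125640, 43125550, 43125249)
  )
  promoter_map(
    cpg_positions = pos,
    amplicons = amps,
    snp = list(position = 43125105, ref_base = "A", alt_base = "G",
               bisulfite_safe = TRUE),
    region_id = "promoter_synthetic",
    contig = "chr17",
    strand = "top"
  )
}

#' Read a promoter map from a YAML file
#'
#' The YAML document mirrors the [promoter_map()] arguments:
#' `cpg_positions` (list of coordinates), `amplicons` (list of records with
#' `amplicon_id`, `cpg_lo`, `cpg_hi`, `start`, `end`), `snp` (`position`,
#' `ref_base`, `alt_base`, optional `bisulfite_safe`), and optional
#' `region_id`, `contig`, `strand`.
#'
#' @param path Path to a YAML file.
#' @return A [promoter_map()].
#' @export
read_promoter_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  amps <- dplyr::bind_rows(lapply(cfg$amplicons, tibble::as_tibble))
  promoter_map(
    cpg_positions = unlist(cfg$cpg_positions),
    amplicons = amps,
    snp = cfg$snp,
    region_id = cfg$region_id %||% "promoter",
    contig = cfg$contig %||% "chr17",
    strand = cfg$strand %||% "top"
  )
}

# CpG indices scored by one amplicon (0-based)
amplicon_cpg_indices <- function(map, amplicon_id) {
  a <- map$amplicons[map$amplicons$amplicon_id == amplicon_id, ]
  if (nrow(a) != 1L) stop("unknown amplicon: ", amplicon_id, call. = FALSE)
  seq(a$cpg_lo, a$cpg_hi)
}

# The two amplicons whose VEFs are averaged into the sample-level measure
# (the biologically relevant CpG14-34 window of the default panel).
central_amplicons <- function(map) {
  ids <- c("CpG14-31", "CpG17-34")
  if (all(ids %in% map$amplicons$amplicon_id)) return(ids)
  # generalised layouts: fall back to all amplicons
  map$amplicons$amplicon_id
}

#' @export
print.promoter_map <- function(x, ...) {
  cat("<promoter_map> ", x$region_id, " (", x$contig, ", ", x$strand,
      " strand)\n", sep = "")
  cat("  CpGs: ", nrow(x$cpgs), " (", x$cpgs$cpg_label[1], "..",
      x$cpgs$cpg_label[nrow(x$cpgs)], ")\n", sep = "")
  cat("  amplicons:\n")
  print(x$amplicons)
  cat("  SNP: ", x$contig, ":", x$snp$position, " ", x$snp$ref_base, "/",
      x$snp$alt_base, " in ", x$snp$amplicon_id, "\n", sep = "")
  invisible(x)
}
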