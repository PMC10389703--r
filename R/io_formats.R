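# IO for the pipeline's external formats: FASTA locus alignments with IUPAC
# heterozygote codes, SNP genotype TSVs with per-SNP metadata, accession and
# trait tables, newick trees and GML haplotype networks.

# IUPAC two-fold ambiguity codes used for diploid Sanger consensus sequences.
IUPAC_HET <- c(
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC"
)
DNA_BASES <- c("A", "C", "G", "T")
MISSING_CHARS <- c("N", "-")
ALLOWED_CHARS <- c(DNA_BASES, names(IUPAC_HET), MISSING_CHARS)

# Reverse map: "AG" -> "R" etc. (alleles sorted alphabetically).
IUPAC_FROM_PAIR <- structure(names(IUPAC_HET), names = unname(IUPAC_HET))

#' Expand a consensus character to its allele pair
#'
#' Unambiguous bases expand to two copies of themselves, two-fold IUPAC codes
#' to their two alleles, `N`/`-` to a pair of `NA`s.
#'
#' @param x character vector of single consensus characters.
#' @return a 2-row character matrix of alleles (columns follow `x`).
#' @keywords internal
iupac_alleles <- function(x) {
  out <- matrix(NA_character_, nrow = 2L, ncol = length(x))
  base <- x %in% DNA_BASES
  out[1L, base] <- x[base]
  out[2L, base] <- x[base]
  het <- x %in% names(IUPAC_HET)
  if (any(het)) {
    pairs <- IUPAC_HET[x[het]]
    out[1L, het] <- substr(pairs, 1L, 1L)
    out[2L, het] <- substr(pairs, 2L, 2L)
  }
  out
}

#' Construct a locus alignment
#'
#' A `locus_alignment` holds equal-length aligned diploid consensus sequences
#' for one nuclear locus: unambiguous bases, two-fold IUPAC heterozygote codes
#' (K, M, R, S, W, Y) and missing states (`N`, `-`).
#'
#' @param locus locus name.
#' @param seqs character matrix (accessions x sites) of single characters, or a
#'   named character vector of sequence strings.
#' @return an object of class `locus_alignment` with fields `locus`, `ids`,
#'   `seq` (character matrix with accession rownames) and `length_bp`.
#' @export
locus_alignment <- function(locus, seqs) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    ids <- names(seqs)
    if (is.null(ids)) stop("sequences must be named by accession id")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- ids[lens != lens[1L]][1L]
      stop("ragged alignment in locus '", locus, "': record '", bad,
           "' has length ", nchar(seqs[bad]), ", expected ", lens[1L])
    }
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(seqs) <- ids
  }
  seqs[] <- toupper(seqs)
  ids <- rownames(seqs)
  if (is.null(ids)) stop("alignment matrix must have accession rownames")
  if (anyDuplicated(ids)) stop("duplicated accession ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- matrix(!(seqs %in% ALLOWED_CHARS), nrow(seqs))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop("illegal character '", seqs[w[1L], w[2L]], "' in record '",
         ids[w[1L]], "' of locus '", locus, "'")
  }
  structure(
    list(locus = locus, ids = ids, seq = seqs, length_bp = ncol(seqs)),
    class = "locus_alignment"
  )
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus, ": ", length(x$ids), " accessions x ",
      x$length_bp, " bp\n", sep = "")
  invisible(x)
}

#' Read a FASTA multiple sequence alignment for one locus
#'
#' Sequences are uppercased on load; the alphabet is restricted to A/C/G/T,
#' the six two-fold IUPAC heterozygote codes, `N` and `-`. Ragged records are
#' a hard error naming the offending record.
#'
#' @param path FASTA file.
#' @param locus_name locus identifier; defaults to the file name stem.
#' @param drop_gap_columns drop every column containing `-` in any record
#'   (reproduces indel-column editing of raw alignments). Default `FALSE`.
#' @return a [locus_alignment].
#' @export
read_fasta_alignment <- function(path, locus_name = NULL,
                                 drop_gap_columns = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(locus_name)) {
    locus_name <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1L], ">"))
    stop("not a FASTA file: ", path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1L))
  if (length(seqs) != length(ids) || !length(ids))
    stop("empty record in FASTA file: ", path)
  names(seqs) <- ids
  aln <- locus_alignment(locus_name, seqs)
  if (drop_gap_columns) {
    gap <- apply(aln$seq == "-", 2L, any)
    if (any(gap)) aln <- locus_alignment(locus_name, aln$seq[, !gap, drop = FALSE])
  }
  aln
}

#' Write a locus alignment to FASTA
#'
#' @param aln a [locus_alignment].
#' @param path output file.
#' @export
write_fasta_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$ids)) {
    writeLines(paste0(">", aln$ids[i]), con)
    writeLines(paste(aln$seq[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Concatenate per-locus alignments
#'
#' Joins loci left to right and records the per-locus column boundaries
#' (0-based half-open) in the `boundaries` attribute.
#'
#' @param alignments list of [locus_alignment] objects.
#' @param id_policy `"intersection"` keeps accessions present in every locus;
#'   `"union_fill_N"` keeps all accessions and pads absent ones with `N`.
#' @param locus name for the concatenated alignment.
#' @return a [locus_alignment] with a `boundaries` attribute (data frame with
#'   columns `locus`, `start`, `end`).
#' @export
concatenate_alignments <- function(alignments,
                                   id_policy = c("intersection", "union_fill_N"),
                                   locus = "concatenated") {
  id_policy <- match.arg(id_policy)
  if (!length(alignments)) stop("no alignments to concatenate")
  id_sets <- lapply(alignments, `[[`, "ids")
  ids <- if (id_policy == "intersection") Reduce(intersect, id_sets)
         else Reduce(union, id_sets)
  if (!length(ids)) stop("empty accession intersection across loci")
  blocks <- lapply(alignments, function(a) {
    m <- matrix("N", nrow = length(ids), ncol = a$length_bp,
                dimnames = list(ids, NULL))
    present <- intersect(ids, a$ids)
    m[present, ] <- a$seq[present, , drop = FALSE]
    m
  })
  lens <- vapply(alignments, `[[`, integer(1L), "length_bp")
  ends <- cumsum(lens)
  boundaries <- data.frame(
    locus = vapply(alignments, `[[`, character(1L), "locus"),
    start = c(0L, ends[-length(ends)]),
    end = ends
  )
  out <- locus_alignment(locus, do.call(cbind, blocks))
  attr(out, "boundaries") <- boundaries
  out
}

#' Construct an accession metadata table
#'
#' @param accession_id,species_label,clade_label,known_hybrid column vectors.
#'   `clade_label` must come from the closed vocabulary
#'   `EA, EU, NA1, NA2, CAL, OUT, UNKNOWN`.
#' @return a data frame of class `accession_table`.
#' @export
accession_table <- function(accession_id, species_label, clade_label,
                            known_hybrid = FALSE) {
  vocab <- c("EA", "EU", "NA1", "NA2", "CAL", "OUT", "UNKNOWN")
  if (anyDuplicated(accession_id)) stop("duplicated accession ids")
  bad <- setdiff(unique(clade_label), vocab)
  if (length(bad)) stop("unknown clade label(s): ", paste(bad, collapse = ", "))
  out <- data.frame(
    accession_id = as.character(accession_id),
    species_label = as.character(species_label),
    clade_label = as.character(clade_label),
    known_hybrid = rep_len(as.logical(known_hybrid), length(accession_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("accession_table", class(out))
  out
}

#' Read / write the accession table (TSV)
#'
#' @param path TSV with columns `accession_id`, `species_label`,
#'   `clade_label`, `known_hybrid`.
#' @return an [accession_table].
#' @export
read_accessions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  accession_table(df$accession_id, df$species_label, df$clade_label,
                  as.logical(df$known_hybrid))
}

#' @rdname read_accessions
#' @param tab an [accession_table].
#' @export
write_accessions <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a SNP genotype matrix
#'
#' Calls are coded as the count of the alternate allele (0, 1, 2) with `NA`
#' for missing. Per-SNP metadata records the discovery panel
#' (`vinifera`, `american`, `muscadinia`) and the genome
#' (`nuclear`, `chloroplast`).
#'
#' @param calls integer matrix, accessions x SNPs, values in {0,1,2,NA};
#'   rownames are accession ids, colnames SNP ids.
#' @param snp_meta data frame with columns `snp_id`, `discovery_panel`,
#'   `genome` and optionally `chromosome`, `position`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, snp_meta) {
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("calls matrix needs accession rownames and SNP colnames")
  if (!identical(colnames(calls), as.character(snp_meta$snp_id)))
    stop("snp_meta rows must match the SNP columns of calls, in order")
  ok <- calls %in% c(0L, 1L, 2L) | is.na(calls)
  if (!all(ok)) stop("genotype calls must be 0, 1, 2 or NA")
  if (!all(snp_meta$discovery_panel %in% c("vinifera", "american", "muscadinia")))
    stop("discovery_panel must be vinifera/american/muscadinia")
  if (!all(snp_meta$genome %in% c("nuclear", "chloroplast")))
    stop("genome must be nuclear/chloroplast")
  structure(
    list(ids = rownames(calls), snp_ids = colnames(calls),
         calls = calls, snp_meta = snp_meta),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$ids), " accessions x ",
      length(x$snp_ids), " SNPs (",
      sum(x$snp_meta$genome == "chloroplast"), " chloroplast); missing ",
      sprintf("%.2f%%", 100 * mean(is.na(x$calls))), "\n", sep = "")
  invisible(x)
}

#' Subset a genotype matrix by SNP ids
#' @param gm a [genotype_matrix].
#' @param snp_ids SNP ids to keep (order preserved).
#' @export
subset_snps <- function(gm, snp_ids) {
  keep <- match(snp_ids, gm$snp_ids)
  if (anyNA(keep)) stop("unknown SNP id(s)")
  genotype_matrix(gm$calls[, keep, drop = FALSE],
                  gm$snp_meta[keep, , drop = FALSE])
}

#' Read / write SNP genotypes with metadata (TSV)
#'
#' The genotype file is accessions x SNPs with an `accession_id` first column;
#' the metadata file has one row per SNP. Cells that are empty or `NA` are
#' missing calls.
#'
#' @param path genotype TSV.
#' @param meta_path SNP metadata TSV.
#' @return a [genotype_matrix].
#' @export
read_genotypes <- function(path, meta_path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  calls <- as.matrix(g[, -1L, drop = FALSE])
  storage.mode(calls) <- "integer"
  rownames(calls) <- g[[1L]]
  genotype_matrix(calls, meta)
}

#' @rdname read_genotypes
#' @param gm a [genotype_matrix].
#' @export
write_genotypes <- function(gm, path, meta_path) {
  df <- data.frame(accession_id = gm$ids, gm$calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gm$snp_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a trait table
#'
#' @param values numeric matrix, accessions x traits, with dimnames.
#' @param trait_type character vector per trait, each in
#'   `length, angle, ratio, morphology, color, pilosity`.
#' @return object of class `trait_table`.
#' @export
trait_table <- function(values, trait_type) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("trait matrix needs accession rownames and trait colnames")
  if (anyDuplicated(colnames(values))) stop("duplicated trait names")
  vocab <- c("length", "angle", "ratio", "morphology", "color", "pilosity")
  if (!all(trait_type %in% vocab))
    stop("trait_type must be one of: ", paste(vocab, collapse = ", "))
  if (length(trait_type) != ncol(values))
    stop("one trait_type per trait required")
  ord <- trait_type %in% c("morphology", "color", "pilosity")
  if (any(ord)) {
    v <- values[, ord, drop = FALSE]
    if (any(stats::na.omit(c(v)) %% 1 != 0))
      stop("ordinal (OIV) traits must be integer-valued")
  }
  structure(list(ids = rownames(values), traits = colnames(values),
                 values = values, trait_type = trait_type),
            class = "trait_table")
}

#' Read / write a trait table (TSV)
#'
#' The TSV has an `accession_id` first column and one column per trait; trait
#' types travel in a companion header line `#types:` if present, else default
#' to `length`. Accessions absent from `accessions` (when given) are dropped
#' with a warning.
#'
#' @param path trait TSV.
#' @param trait_type per-trait types; overrides any `#types:` line.
#' @param accessions optional [accession_table] used to validate ids.
#' @return a [trait_table].
#' @export
read_traits <- function(path, trait_type = NULL, accessions = NULL) {
  first <- readLines(path, n = 1L)
  types_line <- startsWith(first, "#types:")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df[[1L]]
  if (is.null(trait_type)) {
    trait_type <- if (types_line)
      strsplit(sub("^#types:\\s*", "", first), "\t")[[1L]]
    else rep("length", ncol(vals))
  }
  if (!is.null(accessions)) {
    unknown <- setdiff(rownames(vals), accessions$accession_id)
    if (length(unknown)) {
      warning("dropping trait rows for unknown accession(s): ",
              paste(unknown, collapse = ", "))
      vals <- vals[!(rownames(vals) %in% unknown), , drop = FALSE]
    }
  }
  trait_table(vals, trait_type)
}

#' @rdname read_traits
#' @param tt a [trait_table].
#' @export
write_traits <- function(tt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#types:", paste(tt$trait_type, collapse = "\t")), con)
  df <- data.frame(accession_id = tt$ids, tt$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write newick trees
#'
#' Thin wrappers over ape; internal-node labels carry bootstrap percentages
#' (0-100).
#'
#' @param path newick file.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree an `ape::phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Export a haplotype network to GML
#'
#' Nodes carry multiplicity, an `inferred` flag and clade shares; edges carry
#' mutational-step weights.
#'
#' @param net a [haplo_network].
#' @param path output GML file.
#' @export
write_network_gml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "gml")
  invisible(path)
}
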