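# Taxonomic aggregation of classified proteins: flat lineage table I/O,
# non-bacterial exclusion, per-taxon species/sequence summaries with the two
# distinct per-species denominators, and the small-group display filter.

TAX_RANKS <- c("superkingdom", "phylum", "class", "order", "family", "genus")

#' Construct a taxonomy table
#'
#' A flat lineage table: one row per sequence with its species and ordered
#' ranks (superkingdom to genus). Unknown ranks may be empty strings.
#'
#' @param df Data frame with columns `sequence_id`, `species_id` and the
#'   ranks in `TAX_RANKS` (missing rank columns are added empty).
#' @return A `taxonomy_table` data frame.
#' @export
taxonomy_table <- function(df) {
  stopifnot(all(c("sequence_id", "species_id") %in% names(df)))
  if (anyDuplicated(df$sequence_id)) {
    stop("duplicate sequence ids in taxonomy table", call. = FALSE)
  }
  for (r in TAX_RANKS) if (!r %in% names(df)) df[[r]] <- ""
  if (any(df$superkingdom == "")) {
    stop("every sequence needs a superkingdom", call. = FALSE)
  }
  out <- df[, c("sequence_id", "species_id", TAX_RANKS)]
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

#' Read / write a taxonomy TSV
#'
#' Columns: `sequence_id, species_id, superkingdom, phylum, class, order,
#' family, genus`.
#'
#' @param path File path.
#' @param tax A `taxonomy_table` (for writing).
#' @return `read_taxonomy` returns a `taxonomy_table`; `write_taxonomy`
#'   returns `path` invisibly.
#' @export
read_taxonomy <- function(path) {
  taxonomy_table(read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character"))
}

#' @rdname read_taxonomy
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "taxonomy_table"))
  write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

as_annotation_ids <- function(annotations) {
  if (is.character(annotations)) return(annotations)
  if (is.data.frame(annotations)) return(annotations$sequence_id)
  if (inherits(annotations, "proteome_annotation")) {
    return(unique(annotations$hits$sequence_id))
  }
  stop("cannot interpret annotations", call. = FALSE)
}

#' Exclude non-bacterial sequences
#'
#' Partitions annotated sequences by `superkingdom == "Bacteria"`, the
#' survey's restriction of the main analysis, and reports counts per excluded
#' superkingdom.
#'
#' @param annotations Character vector of sequence ids, a data frame with a
#'   `sequence_id` column, or a `proteome_annotation`.
#' @param tax A `taxonomy_table` covering every annotated sequence.
#' @return List with `bacterial` (ids) and `excluded_report` (data frame
#'   `superkingdom, n`); errors listing any id missing from the taxonomy.
#' @export
exclude_nonbacterial <- function(annotations, tax) {
  stopifnot(inherits(tax, "taxonomy_table"))
  ids <- as_annotation_ids(annotations)
  miss <- setdiff(ids, tax$sequence_id)
  if (length(miss)) {
    stop("sequences missing from taxonomy: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sk <- tax$superkingdom[match(ids, tax$sequence_id)]
  bact <- ids[sk == "Bacteria"]
  excl <- ids[sk != "Bacteria"]
  rep_df <- if (length(excl)) {
    tab <- table(sk[sk != "Bacteria"])
    data.frame(superkingdom = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(superkingdom = character(), n = integer(),
               stringsAsFactors = FALSE)
  }
  list(bacterial = bact, excluded_report = rep_df)
}

#' Summarize classified proteins per taxon
#'
#' Groups (optionally class-restricted) sequences by the taxon at the given
#' rank and computes, per taxon: the number of unique species carrying at
#' least one sequence, the number of sequences, the average number of
#' sequences per species *with hits* (the circular-plot ring metric), and the
#' fraction of species relative to all species represented in the (filtered)
#' input. Sorted by decreasing species count.
#'
#' @param annotations Data frame with `sequence_id` and optionally `label`
#'   (architecture class labels), or a character vector of ids.
#' @param tax A `taxonomy_table`.
#' @param rank One of `superkingdom, phylum, class, order, family, genus`.
#' @param class_filter Optional class label to restrict to; unknown labels
#'   error.
#' @return A data frame `taxon, rank, n_species, n_sequences,
#'   avg_per_species, fraction_of_species`.
#' @export
summarize_taxa <- function(annotations, tax, rank = "phylum",
                           class_filter = NULL) {
  stopifnot(inherits(tax, "taxonomy_table"), rank %in% TAX_RANKS)
  if (!is.null(class_filter)) {
    if (!is.data.frame(annotations) || !"label" %in% names(annotations)) {
      stop("class filtering needs annotations with a 'label' column",
           call. = FALSE)
    }
    if (!class_filter %in% annotations$label) {
      stop("unknown class label: ", class_filter, call. = FALSE)
    }
    annotations <- annotations[annotations$label == class_filter, , drop = FALSE]
  }
  ids <- as_annotation_ids(annotations)
  miss <- setdiff(ids, tax$sequence_id)
  if (length(miss)) {
    stop("sequences missing from taxonomy: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rows <- tax[match(ids, tax$sequence_id), , drop = FALSE]
  total_species <- length(unique(rows$species_id))
  sp <- split(rows, rows[[rank]])
  out <- data.frame(
    taxon = names(sp),
    rank = rank,
    n_species = vapply(sp, function(d) length(unique(d$species_id)), integer(1)),
    n_sequences = vapply(sp, nrow, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$avg_per_species <- out$n_sequences / out$n_species
  out$fraction_of_species <- out$n_species / total_species
  out[order(-out$n_species, out$taxon), , drop = FALSE]
}

#' Average number of hit proteins per organism of a taxon
#'
#' Unlike the per-species average of [summarize_taxa()] (whose denominator is
#' species *with* hits), this statistic divides by all distinct species of
#' the taxon present in the proteome collection, including species with zero
#' hits — which is why the taxonomy table must cover the whole collection,
#' not only the annotated sequences.
#'
#' @param annotations Annotated (hit-carrying) sequence ids, as in
#'   [summarize_taxa()].
#' @param tax Collection-wide `taxonomy_table` (the species universe).
#' @param rank Rank name.
#' @param taxon_label Taxon at that rank.
#' @return Average hit count per organism (0 when no species has hits).
#' @export
per_organism_average <- function(annotations, tax, rank, taxon_label) {
  stopifnot(inherits(tax, "taxonomy_table"), rank %in% TAX_RANKS)
  in_taxon <- tax[[rank]] == taxon_label
  n_species <- length(unique(tax$species_id[in_taxon]))
  if (n_species == 0L) {
    stop("taxon '", taxon_label, "' absent at rank ", rank,
         "; the collection-wide species universe is required", call. = FALSE)
  }
  ids <- as_annotation_ids(annotations)
  n_hits <- sum(ids %in% tax$sequence_id[in_taxon])
  n_hits / n_species
}

#' Display filter for small taxonomic groups
#'
#' Retains summaries whose species fraction (default) or sequence fraction is
#' at least `min_fraction`; the survey hides groups below 1.5%. Machine
#' output should always keep the unfiltered set.
#'
#' @param summaries Output of [summarize_taxa()].
#' @param min_fraction Threshold in `[0, 1)`; default 0.015.
#' @param by `"species"` (the circular-plot radian metric) or `"sequences"`.
#' @return The filtered summaries.
#' @export
filter_small_groups <- function(summaries, min_fraction = 0.015,
                                by = c("species", "sequences")) {
  stopifnot(min_fraction >= 0, min_fraction < 1)
  by <- match.arg(by)
  frac <- if (by == "species") summaries$fraction_of_species else
    summaries$n_sequences / sum(summaries$n_sequences)
  summaries[frac >= min_fraction, , drop = FALSE]
}
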