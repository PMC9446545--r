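#' Read a RIME evidence table
#'
#' One row per (protein, replicate, antibody) with the search-engine scores
#' used by the filter. Column names in the file can differ from the
#' canonical ones via \code{col_map}.
#'
#' @param path TSV path.
#' @param col_map named character vector mapping canonical names
#'   (\code{protein_id}, \code{replicate_id}, \code{antibody}, \code{batch},
#'   \code{neg10lgP}, \code{unique_peptides}, \code{spectral_counts}) to the
#'   file's column names; defaults to identity.
#' @return A data frame with the canonical columns.
#' @export
read_rime_evidence <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
  canon <- c("protein_id", "replicate_id", "antibody", "batch",
             "neg10lgP", "unique_peptides", "spectral_counts")
  if (!is.null(col_map)) {
    for (k in names(col_map)) {
      if (!col_map[[k]] %in% names(tab))
        stop("mapped column '", col_map[[k]], "' not in file")
      names(tab)[names(tab) == col_map[[k]]] <- k
    }
  }
  missing <- setdiff(canon, names(tab))
  if (length(missing))
    stop("missing evidence columns: ", paste(missing, collapse = ", "))
  tab[canon]
}

#' Filter RIME evidence into per-replicate interactor sets
#'
#' A protein is positive in a replicate when, in the target-antibody
#' pulldown of that replicate, it reaches \code{-10lgP >= 20}, at least one
#' unique peptide and at least five spectral counts (all inclusive,
#' configurable), and it is not identified -- at any evidence level -- in an
#' IgG control of the same batch.
#'
#' @param evidence data frame with the canonical columns of
#'   \code{\link{read_rime_evidence}}. \code{antibody} must be
#'   \code{"target"} or \code{"IgG"}.
#' @param min_neg10lgP inclusive score threshold (-10 log10 P).
#' @param min_unique_peptides inclusive unique-peptide threshold.
#' @param min_spectral_counts inclusive spectral-count threshold.
#' @return A named list of character vectors, one sorted set of positive
#'   protein ids per replicate present in the target rows.
#' @export
filter_evidence <- function(evidence, min_neg10lgP = 20,
                            min_unique_peptides = 1,
                            min_spectral_counts = 5) {
  req <- c("protein_id", "replicate_id", "antibody", "batch", "neg10lgP",
           "unique_peptides", "spectral_counts")
  stopifnot(all(req %in% names(evidence)))
  ab <- evidence$antibody
  bad <- !(ab %in% c("target", "IgG"))
  if (any(bad))
    stop("unknown antibody label '", ab[which(bad)[1L]],
         "' (expected 'target' or 'IgG')")
  igg <- evidence[ab == "IgG", , drop = FALSE]
  igg_keys <- unique(paste(igg$protein_id, igg$batch, sep = "\r"))
  tgt <- evidence[ab == "target", , drop = FALSE]
  pass <- tgt$neg10lgP >= min_neg10lgP &
    tgt$unique_peptides >= min_unique_peptides &
    tgt$spectral_counts >= min_spectral_counts &
    !(paste(tgt$protein_id, tgt$batch, sep = "\r") %in% igg_keys)
  reps <- sort(unique(tgt$replicate_id))
  out <- lapply(reps, function(r)
    sort(unique(tgt$protein_id[pass & tgt$replicate_id == r])))
  names(out) <- reps
  out
}

#' Three-set Venn region counts
#'
#' Counts the seven non-empty intersection regions of three replicate sets
#' plus their union (the "detected in at least one sample" tally).
#'
#' @param sets a named list of exactly three character vectors.
#' @return Named integer vector: the three exclusive regions, the three
#'   pairwise-only regions, the triple intersection, and \code{union}.
#' @export
replicate_venn <- function(sets) {
  stopifnot(is.list(sets), length(sets) == 3L)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("Rep", 1:3)
  sets <- lapply(sets, unique)
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  if (length(all_ids) == 0L)
    member <- matrix(logical(0), ncol = 3L,
                     dimnames = list(NULL, names(sets)))
  member <- matrix(member, ncol = 3L, dimnames = list(NULL, names(sets)))
  pat <- apply(member, 1L, function(m) paste(as.integer(m), collapse = ""))
  nm <- names(sets)
  region_names <- c(
    "100" = paste0(nm[1], "_only"), "010" = paste0(nm[2], "_only"),
    "001" = paste0(nm[3], "_only"),
    "110" = paste(nm[1], nm[2], sep = "_"),
    "101" = paste(nm[1], nm[3], sep = "_"),
    "011" = paste(nm[2], nm[3], sep = "_"),
    "111" = paste(nm[1], nm[2], nm[3], sep = "_"))
  counts <- vapply(names(region_names), function(p) sum(pat == p),
                   integer(1))
  out <- setNames(as.integer(counts), region_names)
  c(out, union = length(all_ids))
}
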