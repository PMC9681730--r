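# Curation, labeling, splitting and class-rebalancing of degradation records.

MANIFEST_COLUMNS <- c("record_id", "poi_name", "e3_name", "poi_structure",
                      "poi_ligand", "e3_structure", "e3_ligand", "warhead",
                      "linker_smiles", "dc50_nM", "dmax_pct")

#' Activity cutoff scheme
#'
#' The default labels a compound a good degrader when DC50 < 100 nM and
#' Dmax > 80%; the relaxed alternative uses 1000 nM and 70%.
#' @param dc50_max DC50 upper cutoff in nM (exclusive).
#' @param dmax_min Dmax lower cutoff in percent (exclusive).
#' @return a `cutoff_scheme` list.
#' @export
cutoff_scheme <- function(dc50_max = 100, dmax_min = 80) {
  stopifnot(dc50_max > 0, dmax_min > 0)
  structure(list(dc50_max = dc50_max, dmax_min = dmax_min),
            class = "cutoff_scheme")
}

#' @rdname cutoff_scheme
#' @export
relaxed_cutoff_scheme <- function() cutoff_scheme(1000, 70)

#' Label degradation records
#'
#' A record is `active` iff DC50 is strictly below `dc50_max` and Dmax
#' strictly above `dmax_min`; a missing DC50 or Dmax yields `inactive`.
#' Range-valued DC50 entries such as `"<10"` are resolved by taking the
#' bound as the value.
#'
#' @param records data.frame with columns `dc50_nM` and `dmax_pct`.
#' @param scheme a [cutoff_scheme()].
#' @return `records` with a `label` column (`"active"`/`"inactive"`).
#' @export
label_records <- function(records, scheme = cutoff_scheme()) {
  dc50 <- parse_dc50(records$dc50_nM)
  dmax <- suppressWarnings(as.numeric(records$dmax_pct))
  active <- !is.na(dc50) & !is.na(dmax) &
    dc50 < scheme$dc50_max & dmax > scheme$dmax_min
  records$label <- ifelse(active, "active", "inactive")
  records
}

#' @rdname label_records
#' @param dc50,dmax scalar DC50 (nM) and Dmax (%) values, possibly `NA`.
#' @export
label_record <- function(dc50, dmax, scheme = cutoff_scheme()) {
  label_records(data.frame(dc50_nM = dc50, dmax_pct = dmax), scheme)$label
}

parse_dc50 <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^[<>]=?", "", x)        # "<10 nM" -> bound as value
  x <- sub("\\s*nM$", "", x, ignore.case = TRUE)
  suppressWarnings(as.numeric(x))
}

#' Read / write a dataset manifest
#'
#' The manifest is a UTF-8 CSV with header columns record_id, poi_name,
#' e3_name, poi_structure, poi_ligand, e3_structure, e3_ligand, warhead,
#' linker_smiles, dc50_nM, dmax_pct and optionally label.
#' @param path CSV file path.
#' @return a data.frame of records.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(record_id = "character"))
  missing <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing))
    stop("manifest ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' @rdname read_manifest
#' @param records data.frame of records.
#' @export
write_manifest <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Random split into partitions
#'
#' Records are uniformly permuted under `seed` and sliced contiguously by
#' the ratios. Sizes are each ratio's floor, with the remainder assigned to
#' the first partition, so partitions are disjoint and exhaustive.
#' @param records data.frame of records.
#' @param ratios proportions summing to 1, e.g. `c(0.8, 0.1, 0.1)`.
#' @param seed integer RNG seed.
#' @return list of data.frames, one per ratio.
#' @export
split_records <- function(records, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- nrow(records)
  if (n == 0L) stop("no records to split")
  if (n < length(ratios)) stop("fewer records than partitions")
  stopifnot(abs(sum(ratios) - 1) < 1e-8, all(ratios > 0))
  sizes <- floor(ratios * n)
  sizes[1L] <- sizes[1L] + (n - sum(sizes))
  set.seed(seed)
  perm <- sample.int(n)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(sizes), function(k) {
    part <- records[perm[starts[k]:ends[k]], , drop = FALSE]
    rownames(part) <- NULL
    part
  })
}

parse_split_ratios <- function(text) {
  parts <- as.numeric(strsplit(text, ":", fixed = TRUE)[[1]])
  if (any(is.na(parts)) || length(parts) < 2L)
    stop("cannot parse split specification '", text, "'")
  parts / sum(parts)
}

#' Under-sample the majority class
#'
#' Keeps every active record and subsamples inactive records uniformly
#' without replacement down to the active count (e.g. 988:1844 becomes
#' 988:988).
#' @param records labeled data.frame.
#' @param seed integer RNG seed.
#' @return the rebalanced data.frame.
#' @export
undersample <- function(records, seed = 1L) {
  act <- records[records$label == "active", , drop = FALSE]
  ina <- records[records$label == "inactive", , drop = FALSE]
  if (nrow(act) > nrow(ina))
    stop("undersampling expects inactive records to be the majority")
  set.seed(seed)
  keep <- sample.int(nrow(ina), nrow(act))
  out <- rbind(act, ina[keep, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Over-sample the minority class
#'
#' Keeps every record and resamples active records with replacement until
#' the counts are equal (e.g. 988:1844 becomes 1844:1844). Every original
#' record remains present at least once.
#' @param records labeled data.frame.
#' @param seed integer RNG seed.
#' @return the rebalanced data.frame (a multiset of the input rows).
#' @export
oversample <- function(records, seed = 1L) {
  act <- records[records$label == "active", , drop = FALSE]
  ina <- records[records$label == "inactive", , drop = FALSE]
  if (nrow(act) > nrow(ina))
    stop("oversampling expects active records to be the minority")
  set.seed(seed)
  extra <- nrow(ina) - nrow(act)
  idx <- if (extra > 0L) sample.int(nrow(act), extra, replace = TRUE)
         else integer(0)
  out <- rbind(records, act[idx, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Per-class loss weights
#'
#' `normal` weighs both classes 1; `weighted` multiplies the loss of active
#' samples by 2 and leaves inactive samples unchanged.
#' @param mode `"normal"` or `"weighted"`.
#' @return named numeric vector `c(active = , inactive = )`.
#' @export
class_loss_weights <- function(mode = c("normal", "weighted")) {
  mode <- match.arg(mode)
  if (mode == "normal") c(active = 1, inactive = 1) else
    c(active = 2, inactive = 1)
}

#' Write split membership as JSON
#' @param parts list of record data.frames (from [split_records()]).
#' @param path JSON file path.
#' @param names_ partition names.
#' @return `path`, invisibly.
#' @export
write_split_json <- function(parts, path,
                             names_ = c("train", "validation", "test")[seq_along(parts)]) {
  jsonlite::write_json(stats::setNames(lapply(parts, `[[`, "record_id"),
                                       names_), path)
  invisible(path)
}
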