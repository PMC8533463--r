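# Internal helpers shared across modules.

# A wide expression tibble has feature ids in the first column and one column
# per sample. These helpers move between that representation and a plain
# numeric matrix with rownames.

expr_to_matrix <- function(x, id_col = NULL) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) {
      rownames(x) <- sprintf("feature_%d", seq_len(nrow(x)))
    }
    return(x)
  }
  stopifnot(is.data.frame(x))
  id_col <- id_col %||% names(x)[1]
  ids <- as.character(x[[id_col]])
  m <- as.matrix(x[setdiff(names(x), id_col)])
  if (!is.numeric(m)) {
    abort("expression table has non-numeric sample columns")
  }
  rownames(m) <- ids
  m
}

matrix_to_expr <- function(m, id_col = "feature_id") {
  out <- cbind(data.frame(..id.. = rownames(m), stringsAsFactors = FALSE),
               as.data.frame(m, stringsAsFactors = FALSE))
  names(out)[1] <- id_col
  rownames(out) <- NULL
  as_tibble(out)
}

# Per-sample group labels aligned to the columns of an expression matrix.
sample_groups <- function(samples, sample_ids) {
  stopifnot(is.data.frame(samples), all(c("sample_id", "group") %in% names(samples)))
  idx <- match(sample_ids, samples$sample_id)
  if (anyNA(idx)) {
    abort(paste0(
      "samples sheet is missing ",
      sum(is.na(idx)), " sample id(s), e.g. ",
      paste(head(sample_ids[is.na(idx)], 3), collapse = ", ")
    ))
  }
  samples$group[idx]
}

# Deterministic per-stage seed stream: a small integer hash of the label folded
# into the master seed, kept below .Machine$integer.max so set.seed() accepts it.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

`%||%` <- rlang::`%||%`
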