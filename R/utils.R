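# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic fan-out of a master seed into per-stage seeds. Keeps results
# of independent stages reproducible in isolation. Always < 2^31.
derive_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 1103L + h * 12289L) %% 2147483399) + 1L
}

# Coerce a samples-by-features table to a numeric matrix with sample_id
# rownames. Accepts a tibble/data.frame with a sample_id first column, or a
# matrix with rownames.
as_feature_matrix <- function(x, what = "matrix") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort(paste0(what, " matrix must have sample_id rownames"))
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.data.frame(x)) {
    if (!"sample_id" %in% names(x)) {
      abort(paste0(what, " data frame must have a sample_id column"))
    }
    ids <- as.character(x$sample_id)
    if (anyDuplicated(ids)) abort(paste0("duplicate sample_id in ", what))
    m <- as.matrix(x[setdiff(names(x), "sample_id")])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    return(m)
  }
  abort(paste0(what, " must be a matrix or data frame"))
}

# Matrix back to the tibble convention used throughout: sample_id + columns.
matrix_to_tbl <- function(m) {
  dplyr::bind_cols(tibble(sample_id = rownames(m)), as_tibble(m))
}

# Align rows of a feature matrix to a vector of sample ids, strict.
align_rows <- function(m, ids, what = "matrix") {
  missing <- setdiff(ids, rownames(m))
  if (length(missing) > 0) {
    abort(paste0(what, ": missing samples: ", paste(head(missing, 3), collapse = ", ")))
  }
  m[ids, , drop = FALSE]
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) && x >= 0

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    abort(paste0(name, " must be a single number strictly between 0 and 1"))
  }
  invisible(x)
}
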