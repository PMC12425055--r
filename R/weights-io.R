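# Portable weight files: tab-separated gpc_index/cpg/weight with `#` header
# lines carrying metadata. No timestamps, so identical training runs give
# bit-identical files.

#' Write and read portable MPS weight files
#'
#' The weight file is the shareable artifact: tab-separated columns
#' `gpc_index`, `cpg`, `weight` (full double precision), preceded by
#' `#`-prefixed header lines recording the beta-value scale, the intercept
#' policy (intercepts are stored but excluded from scores), and per-model
#' metadata (stage, penalty, intercept, CpG universe size). The round trip
#' `write_weights()` then `read_weights()` is lossless, including models
#' with no nonzero weights.
#'
#' @param models An `mps_model_set`, a list of `mps_model`s, or a single
#'   model.
#' @param path File path.
#'
#' @return `write_weights()` returns `path` invisibly; `read_weights()`
#'   returns an `mps_model_set`.
#' @export
write_weights <- function(models, path) {
  if (inherits(models, "mps_model")) models <- list(models)
  fmt <- function(x) sprintf("%.17g", x)
  hdr <- c("# mpscore weight file v1",
           "# scale: beta_value",
           "# intercept_policy: stored_not_scored")
  for (m in models) {
    hdr <- c(hdr, sprintf(
      "# model gpc=%d stage=%d lambda=%s intercept=%s n_universe=%d seed=%s",
      m$gpc_index, m$stage, fmt(m$lambda), fmt(m$intercept),
      length(m$cpg_universe),
      as.character(m$training_meta$master_seed %||% m$training_meta$seed %||% NA)))
  }
  body <- "gpc_index\tcpg\tweight"
  for (m in models) {
    if (length(m$weights) > 0) {
      body <- c(body, sprintf("%d\t%s\t%s", m$gpc_index, names(m$weights),
                              fmt(m$weights)))
    }
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  meta_lines <- grep("^# model ", lines, value = TRUE)
  parse_field <- function(line, key) {
    m <- regmatches(line, regexec(paste0(key, "=([^ ]+)"), line))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  num_or_na <- function(x) {
    if (is.na(x) || x %in% c("NA", "nan", "-nan")) NA_real_ else as.numeric(x)
  }
  meta <- lapply(meta_lines, function(l) {
    list(gpc = as.integer(parse_field(l, "gpc")),
         stage = as.integer(parse_field(l, "stage")),
         lambda = num_or_na(parse_field(l, "lambda")),
         intercept = num_or_na(parse_field(l, "intercept")))
  })
  body <- lines[!is_hdr]
  if (length(body) == 0 || body[1] != "gpc_index\tcpg\tweight") {
    abort(paste0("malformed weight file (line ", sum(is_hdr) + 1,
                 "): missing column header"))
  }
  rows <- body[-1]
  parts <- strsplit(rows, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0) {
    abort(paste0("malformed weight file at line ",
                 sum(is_hdr) + 1 + bad[1], ": expected 3 fields"))
  }
  df <- tibble(
    gpc_index = as.integer(vapply(parts, `[[`, "", 1)),
    cpg = vapply(parts, `[[`, "", 2),
    weight = as.numeric(vapply(parts, `[[`, "", 3))
  )
  if (anyNA(df$gpc_index) || anyNA(df$weight)) {
    abort("malformed weight file: non-numeric gpc_index or weight")
  }
  if (anyDuplicated(df[c("gpc_index", "cpg")])) {
    d <- df[duplicated(df[c("gpc_index", "cpg")]), ]
    abort(paste0("duplicate CpG row in weight file: ", d$cpg[1],
                 " (gpc ", d$gpc_index[1], ")"))
  }
  gpc_ids <- if (length(meta) > 0) {
    vapply(meta, `[[`, 1L, "gpc")
  } else {
    sort(unique(df$gpc_index))
  }
  models <- lapply(seq_along(gpc_ids), function(i) {
    k <- gpc_ids[i]
    rows_k <- df[df$gpc_index == k, ]
    w <- setNames(rows_k$weight, rows_k$cpg)
    mi <- if (length(meta) >= i) meta[[i]] else {
      list(stage = 2L, lambda = NA_real_, intercept = 0)
    }
    new_mps_model(k, w, mi$intercept, mi$stage, mi$lambda,
                  cpg_universe = names(w),
                  training_meta = list(source = path))
  })
  structure(models, class = "mps_model_set")
}
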