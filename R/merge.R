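#' Merge a set of read pairs
#'
#' The workhorse: runs the full overlap-detection cascade (and, in the
#' k-mer modes, tail extension with REM/RSEM acceptance and the optional
#' k-mer filter) over every pair and builds consensus reads for accepted
#' merges. Results are independent of how the input is batched.
#'
#' @param pairs A `pe_pairs` object.
#' @param profile A [sensitivity_profile()] (or a preset name).
#' @param mode `"default"` (overlap only), `"rem"`, or `"rsem"`.
#' @param adapter1,adapter2 Optional adapter sequences for the read-through
#'   check.
#' @param table A [kmer_table()]; built from `pairs` on the fly when a
#'   k-mer mode or `kfilter` needs one and none is given.
#' @param k Word size used when the table is built here.
#' @param extend_len Maximum tail extension in bases (k-mer modes).
#' @param min_depth Minimum successor depth during extension.
#' @param kfilter Depth for the post-merge k-mer filter; 0 disables it.
#' @param qext Quality for extension-derived bases.
#' @param build_reads Build merged consensus reads (set `FALSE` for
#'   insert-size-histogram-only runs).
#' @return A `merge_result`: list with `status` (factor over the rejection
#'   vocabulary), `insert` (integer, `NA` when unmerged), `merged`
#'   (`pe_reads` of accepted merges, headers inherited from read 1),
#'   `merged_idx` (their pair indices), `n` and `counts`.
#' @examples
#' g <- generate_genome(20000, seed = 1)
#' p <- simulate_pairs(g, n_pairs = 200, seed = 2)
#' res <- merge_pairs(p)
#' summary(res)
#' @export
merge_pairs <- function(pairs, profile = sensitivity_profile(),
                        mode = c("default", "rem", "rsem"),
                        adapter1 = NULL, adapter2 = NULL, table = NULL,
                        k = 31L, extend_len = 50L, min_depth = 2L,
                        kfilter = 0L, qext = 20L, build_reads = TRUE) {
  stopifnot(inherits(pairs, "pe_pairs"))
  if (is.character(profile)) profile <- sensitivity_profile(profile)
  mode <- match.arg(mode)
  mode_code <- match(mode, c("default", "rem", "rsem")) - 1L
  a1 <- if (is.null(adapter1)) "" else toupper(adapter1)
  a2 <- if (is.null(adapter2)) "" else toupper(adapter2)
  needs_table <- mode_code > 0L || kfilter > 0L
  if (needs_table && is.null(table)) table <- kmer_table(pairs, k)
  tab_ptr <- if (needs_table) table$ptr else NULL

  res <- cpp_merge_batch(pairs$r1$seq, pairs$r1$qual, pairs$r2$seq,
                         pairs$r2$qual, profile, a1, a2, mode_code, tab_ptr,
                         as.integer(extend_len), as.integer(min_depth),
                         as.integer(kfilter), as.integer(qext), build_reads)

  status <- status_factor(res$status)
  merged_idx <- which(res$status == 0L)
  merged <- if (build_reads && length(merged_idx))
    new_read_set(pairs$r1$id[merged_idx], unlist(res$seq[merged_idx]),
                 res$qual[merged_idx])
  else new_read_set(character(), character(), list())

  structure(list(status = status, insert = res$insert, merged = merged,
                 merged_idx = merged_idx, n = length(pairs),
                 counts = table(status), mode = mode,
                 preset = profile$preset_name),
            class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  cat(sprintf("<merge_result> %d pairs, mode=%s, preset=%s\n", x$n, x$mode,
              x$preset))
  nm <- sum(x$status == "merged")
  cat(sprintf("  merged: %d (%.2f%%)\n", nm, 100 * nm / max(x$n, 1)))
  rej <- x$counts[names(x$counts) != "merged" & x$counts > 0]
  if (length(rej))
    cat("  rejected:", paste(sprintf("%s=%d", names(rej), rej),
                             collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.merge_result <- function(object, ...) {
  out <- list(n = object$n, counts = object$counts,
              merged_rate = sum(object$status == "merged") / max(object$n, 1),
              insert_summary = if (any(!is.na(object$insert)))
                summary(object$insert[!is.na(object$insert)]) else NULL)
  class(out) <- "summary.merge_result"
  out
}

#' @export
print.summary.merge_result <- function(x, ...) {
  cat(sprintf("merge summary: %d pairs, %.2f%% merged\n", x$n,
              100 * x$merged_rate))
  print(x$counts)
  if (!is.null(x$insert_summary)) {
    cat("insert sizes of merged reads:\n")
    print(x$insert_summary)
  }
  invisible(x)
}

#' Insert-size histogram of accepted merges
#'
#' @param x A `merge_result` (or an integer vector of insert sizes with
#'   `NA` for unmerged pairs).
#' @return A data.frame with columns `insert` and `count`, sorted by
#'   insert size; the counts sum to the number of merged pairs.
#' @export
insert_histogram <- function(x) {
  ins <- if (inherits(x, "merge_result")) x$insert else x
  ins <- ins[!is.na(ins)]
  if (!length(ins))
    return(data.frame(insert = integer(), count = integer()))
  tab <- table(ins)
  data.frame(insert = as.integer(names(tab)), count = as.integer(tab))
}
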