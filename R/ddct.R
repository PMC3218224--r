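#' Comparative-Ct relative expression
#'
#' Computes relative expression of a target transcript in knockdown versus
#' control by the comparative Ct method: with
#' dCt = Ct(target) - Ct(reference) in each condition and
#' ddCt = dCt(knockdown) - dCt(control), relative expression is 2^-ddCt
#' (1 = unchanged, 0.5 = halved; knockdown efficiency is 1 minus this).
#' The reference transcript (e.g. rp49) must be measured alongside every
#' target.
#'
#' @param target_kd,ref_kd Ct of target and reference in the knockdown
#'   condition.
#' @param target_ctrl,ref_ctrl Ct of target and reference in the control
#'   condition.
#' @return relative expression (fraction of control), vectorized.
#' @examples
#' relative_expression_ddct(20, 15, 20, 15)      # 1: no change
#' relative_expression_ddct(21, 15, 20, 15)      # 0.5
#' relative_expression_ddct(23.32, 15, 20, 15)   # ~0.10, i.e. ~90% knockdown
#' @export
relative_expression_ddct <- function(target_kd, ref_kd, target_ctrl,
                                     ref_ctrl) {
  args <- list(target_kd, ref_kd, target_ctrl, ref_ctrl)
  if (any(vapply(args, function(a) any(is.na(a)) || !length(a), TRUE)))
    stop("all four Ct values (target and reference, both conditions) ",
         "are required", call. = FALSE)
  if (any(unlist(args) <= 0))
    stop("Ct values must be positive", call. = FALSE)
  ddct <- (target_kd - ref_kd) - (target_ctrl - ref_ctrl)
  2^(-ddct)
}

#' Relative expression from a Ct measurement table
#'
#' Averages replicate Ct values per gene and condition and applies
#' [relative_expression_ddct()] against the reference transcript.
#'
#' @param ct data.frame with columns `gene, condition, ct_target, ct_ref`
#'   (and optionally `replicate`); `condition` must contain `control` and
#'   `knockdown` rows for every gene.
#' @return data.frame `gene, relative_expression`.
#' @export
ddct_table <- function(ct) {
  need <- c("gene", "condition", "ct_target", "ct_ref")
  if (!all(need %in% names(ct)))
    stop("ct table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  genes <- unique(ct$gene)
  out <- lapply(genes, function(g) {
    kd <- ct[ct$gene == g & ct$condition == "knockdown", ]
    ctl <- ct[ct$gene == g & ct$condition == "control", ]
    if (!nrow(kd) || !nrow(ctl))
      stop("gene ", g, " lacks measurements in one condition", call. = FALSE)
    data.frame(gene = g,
               relative_expression = relative_expression_ddct(
                 mean(kd$ct_target), mean(kd$ct_ref),
                 mean(ctl$ct_target), mean(ctl$ct_ref)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
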