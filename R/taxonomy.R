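# Taxonomy module: combine perturbation-conditioned differential calls
# across the two dominant-negative clones with peak-to-gene assignments to
# label every gene as a direct/indirect activated/repressed target,
# nonfunctional bound, unaffected, or other.

#' Build the contrast panel
#'
#' Computes the per-gene differential tables the classifier consumes:
#' parental activation contrasts (1 h vs 0 h, 4 h vs 0 h, `-Tet`) and, for
#' each clone and each post-stimulation time point, the perturbation
#' contrast `+Tet` vs `-Tet` at that time.
#'
#' @param expression a [kb_expression] object.
#' @param test differential engine with the signature of
#'   [test_differential()] (the pluggable contract).
#' @param times post-stimulation time points to contrast (default 1 and 4 h).
#' @param fdr significance cutoff stored with the panel (default 0.05).
#' @return object of class `kb_contrast_panel`: nested list
#'   `parental[[time]]` and `<clone>[[time]]` of (gene_id, log2FC, p, fdr)
#'   tables.
#' @export
contrast_panel <- function(expression, test = test_differential,
                           times = c(1, 4), fdr = 0.05) {
  s <- expression$samples
  cols <- function(cell, tet, time)
    s$sample[s$cell_line == cell & s$tet == tet & s$time == time]
  panel <- list(parental = list(), clone1 = list(), clone2 = list())
  for (t in times) {
    panel$parental[[as.character(t)]] <-
      test(expression, cols("parental", "minus", t),
           cols("parental", "minus", 0))
    for (cl in c("clone1", "clone2"))
      panel[[cl]][[as.character(t)]] <-
        test(expression, cols(cl, "plus", t), cols(cl, "minus", t))
  }
  structure(list(contrasts = panel, times = times, fdr = fdr),
            class = "kb_contrast_panel")
}

#' @export
print.kb_contrast_panel <- function(x, ...) {
  cat("kb_contrast_panel: times", paste(x$times, collapse = "/"),
      "h, FDR cutoff", x$fdr, "\n")
  invisible(x)
}

#' Putative targets from inducible transcription plus binding
#'
#' The first-pass target logic: genes changing at least `fc_threshold`-fold
#' (up or down) at 1 or 4 h of stimulation that also carry an assigned
#' inducible RELA peak.
#'
#' @param panel a [contrast_panel()] object (parental contrasts are used).
#' @param rela_genes character vector of genes with an assigned reproducible
#'   inducible RELA peak.
#' @param fc_threshold fold-change threshold (default 2, i.e.
#'   `|log2FC| >= 1`).
#' @return list with `bound_up` and `bound_down` gene-id vectors.
#' @export
putative_targets <- function(panel, rela_genes, fc_threshold = 2) {
  lt <- log2(fc_threshold)
  par <- panel$contrasts$parental
  ids <- par[[1]]$gene_id
  up <- Reduce(`|`, lapply(par, function(d) d$log2FC >= lt))
  down <- Reduce(`|`, lapply(par, function(d) d$log2FC <= -lt))
  list(bound_up = ids[up & ids %in% rela_genes],
       bound_down = ids[down & ids %in% rela_genes])
}

#' Classify genes into the target taxonomy
#'
#' A gene is dn-reduced if its stimulated expression is significantly lower
#' (`FDR <= fdr`, negative fold change) under the dominant-negative
#' perturbation in *both* clones at at least one common time point; it is
#' then a direct activated target (`Ad`) if it carries an assigned RELA peak
#' and an indirect one (`Ai`) otherwise.  dn-increased genes become
#' `Rd`/`Ri` analogously.  Genes with no significant call in any activation
#' or perturbation contrast are `unaffected` (`nonfunctional_bound` when
#' RELA-bound), and everything else - including genes responding in a single
#' clone only, or with conflicting directions - is `other`.
#'
#' @param panel a [contrast_panel()] object covering both clones.
#' @param rela_genes genes with an assigned reproducible inducible RELA
#'   peak.
#' @param fdr significance cutoff (default 0.05).
#' @return object of class `kb_taxonomy`: data.frame with `gene_id`,
#'   `class`, `robust` (NA until [robust_flag()]), `pattern_label` (NA until
#'   [pattern_labels()]), and evidence columns `dn_reduced`, `dn_increased`,
#'   `activation_responsive`, `min_tet_fdr`.
#' @export
classify_targets <- function(panel, rela_genes, fdr = 0.05) {
  con <- panel$contrasts
  ids <- con$parental[[1]]$gene_id
  for (cl in c("clone1", "clone2")) {
    if (is.null(con[[cl]]) || !length(con[[cl]]))
      stop("contrast panel is missing clone: ", cl)
    for (tab in con[[cl]])
      if (!setequal(tab$gene_id, ids))
        stop("gene(s) present in only one clone's panel: ",
             paste(utils::head(setdiff(ids, tab$gene_id), 5),
                   collapse = ", "))
  }
  aligned <- function(tab) tab[match(ids, tab$gene_id), ]
  tt <- as.character(panel$times)

  red <- inc <- rep(FALSE, length(ids))
  min_tet_fdr <- rep(1, length(ids))
  for (t in tt) {
    c1 <- aligned(con$clone1[[t]]); c2 <- aligned(con$clone2[[t]])
    red <- red | (c1$fdr <= fdr & c1$log2FC < 0 &
                  c2$fdr <= fdr & c2$log2FC < 0)
    inc <- inc | (c1$fdr <= fdr & c1$log2FC > 0 &
                  c2$fdr <= fdr & c2$log2FC > 0)
    min_tet_fdr <- pmin(min_tet_fdr, pmax(c1$fdr, c2$fdr))
  }
  any_tet_sig <- rep(FALSE, length(ids))
  for (t in tt) for (cl in c("clone1", "clone2")) {
    d <- aligned(con[[cl]][[t]])
    any_tet_sig <- any_tet_sig | d$fdr <= fdr
  }
  act_sig <- Reduce(`|`, lapply(con$parental,
                                function(d) aligned(d)$fdr <= fdr))

  bound <- ids %in% rela_genes
  class <- rep("other", length(ids))
  class[red & !inc & bound] <- "Ad"
  class[red & !inc & !bound] <- "Ai"
  class[inc & !red & bound] <- "Rd"
  class[inc & !red & !bound] <- "Ri"
  quiet <- !any_tet_sig & !act_sig
  class[quiet & bound] <- "nonfunctional_bound"
  class[quiet & !bound] <- "unaffected"

  out <- data.frame(gene_id = ids, class = class,
                    robust = NA, pattern_label = NA_character_,
                    dn_reduced = red, dn_increased = inc,
                    activation_responsive = act_sig,
                    min_tet_fdr = min_tet_fdr,
                    stringsAsFactors = FALSE)
  class(out) <- c("kb_taxonomy", "data.frame")
  out
}

#' @export
print.kb_taxonomy <- function(x, ...) {
  cat("kb_taxonomy:", nrow(x), "genes\n")
  print(table(class = x$class))
  invisible(x)
}

#' @export
summary.kb_taxonomy <- function(object, ...) {
  tab <- table(class = object$class)
  cat("Target taxonomy over", nrow(object), "genes\n")
  print(tab)
  if (!all(is.na(object$robust))) {
    cat("\nRobust (>= 2-fold at -Tet) per class:\n")
    print(table(class = object$class[object$robust %in% TRUE]))
  }
  cat("\nPartition identity: |Ad|+|Ai| =", sum(tab[c("Ad", "Ai")],
      na.rm = TRUE), "dn-reduced genes;",
      "|Rd|+|Ri| =", sum(tab[c("Rd", "Ri")], na.rm = TRUE),
      "dn-increased genes\n")
  invisible(tab)
}

#' Flag robustly responding targets
#'
#' A classified target (Ad/Ai/Rd/Ri) is robust when its unperturbed
#' (`-Tet`) stimulation response reaches `threshold`-fold
#' (`|log2FC| >= log2(threshold)`) at 1 or 4 h.
#'
#' @param records a `kb_taxonomy` object.
#' @param panel the [contrast_panel()] (parental fold changes are used).
#' @param threshold fold threshold (default 2; boundary inclusive).
#' @return the records with the `robust` column filled.
#' @export
robust_flag <- function(records, panel, threshold = 2) {
  lt <- log2(threshold)
  par <- panel$contrasts$parental
  big <- Reduce(`|`, lapply(par, function(d)
    abs(d$log2FC[match(records$gene_id, d$gene_id)]) >= lt))
  records$robust <- records$class %in% c("Ad", "Ai", "Rd", "Ri") & big
  records
}

#' Attach kinetic pattern labels
#'
#' Combines per-class cluster assignments into labels such as `"3Ad"`
#' (pattern 3 among the direct activated targets).
#'
#' @param records a `kb_taxonomy` object.
#' @param assignments named list (class -> named integer vector of cluster
#'   labels, e.g. from [kmeans_patterns()]`$cluster`) for each clustered
#'   class.
#' @return the records with `pattern_label` filled for clustered classes;
#'   a gene of a clustered class missing from its assignment raises an
#'   error.
#' @export
pattern_labels <- function(records, assignments) {
  for (cls in names(assignments)) {
    members <- records$gene_id[records$class == cls]
    a <- assignments[[cls]]
    missing <- setdiff(members, names(a))
    if (length(missing))
      stop("unclustered gene(s) in class ", cls, ": ",
           paste(utils::head(missing, 5), collapse = ", "))
    records$pattern_label[match(members, records$gene_id)] <-
      sprintf("%d%s", a[members], cls)
  }
  records
}

#' Combine responses into four perturbation-response groups
#'
#' Partitions the activation- or perturbation-responsive genes into the four
#' summary groups: `I` = down-regulated by the dominant negative
#' (dn-reduced, Ad/Ai), `II` = up-regulated by it (Rd/Ri), `III` =
#' stimulation-induced but dn-insensitive, `IV` = stimulation-repressed but
#' dn-insensitive.
#'
#' @param records a `kb_taxonomy` object.
#' @param panel the [contrast_panel()] (parental direction is used for
#'   groups III/IV).
#' @param fdr significance cutoff for the activation calls.
#' @return data.frame `gene_id`, `group` over the responsive genes (the
#'   groups partition them).
#' @export
combined_pattern_groups <- function(records, panel, fdr = 0.05) {
  par <- panel$contrasts$parental
  lfc <- sapply(par, function(d) d$log2FC[match(records$gene_id,
                                                d$gene_id)])
  sig <- sapply(par, function(d) d$fdr[match(records$gene_id,
                                             d$gene_id)] <= fdr)
  act_up <- rowSums(sig & lfc > 0) > 0
  act_down <- rowSums(sig & lfc < 0) > 0
  group <- rep(NA_character_, nrow(records))
  group[records$class %in% c("Ad", "Ai")] <- "I"
  group[records$class %in% c("Rd", "Ri")] <- "II"
  insens <- is.na(group)
  group[insens & act_up & !act_down] <- "III"
  group[insens & act_down & !act_up] <- "IV"
  keep <- !is.na(group)
  data.frame(gene_id = records$gene_id[keep], group = group[keep],
             stringsAsFactors = FALSE)
}
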