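# Diagnostic plots for run reports.  ggplot2 is suggested, not required:
# these helpers are the only consumers.

#' Plot per-entry alignment quality for a scene
#'
#' Bar chart of the superposition RMSD of every successfully built entry,
#' annotated with the fraction of residue pairs retained by the outlier
#' rejection - a quick screen for entries that aligned badly (wrong chain
#' in the card, unrelated structure, ...).
#'
#' @param scene A `ligand_scene` with at least one built object.
#' @return A ggplot object.
#' @export
plot_alignment_quality <- function(scene) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_alignment_quality needs the ggplot2 package")
  }
  rep <- tidy(scene)
  ok <- rep[rep$status == "ok", ]
  if (nrow(ok) == 0) stop("no built objects to plot")
  ok$pairs_kept <- ok$n_pairs_final / ok$n_pairs_initial
  ggplot2::ggplot(ok, ggplot2::aes(x = stats::reorder(.data$object_name,
                                                      .data$rmsd),
                                   y = .data$rmsd, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d/%d", .data$n_pairs_final, .data$n_pairs_initial)),
      hjust = -0.1, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "superposition RMSD (Å)",
                  fill = "group",
                  title = "Alignment quality per entry",
                  subtitle = "labels: residue pairs kept / paired") +
    ggplot2::theme_minimal()
}
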