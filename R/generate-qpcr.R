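## Synthetic RT-qPCR Ct tables with exact ground-truth fold changes.

#' Generate a synthetic Ct table
#'
#' One row per (group, gene, replicate) with Gaussian replicate noise on
#' the Ct values.  The noiseless Ct values encode the preset's
#' delta-Ct design exactly, so the expected `2^(-ddCt)` between any two
#' groups equals the preset fold change by construction.
#'
#' @param preset A [qpcr_preset()].
#' @param n_replicates Biological replicates per group (>= 2).
#' @param seed Integer seed; same `(preset, n_replicates, seed)` gives an
#'   identical table.
#' @param noise_sd Replicate noise in Ct units; defaults to the preset
#'   value (use 0 for a noiseless table).
#' @return A data frame with columns `sample_id`, `group`, `gene`, `ct`.
#' @export
#' @examples
#' ct <- generate_ct_table(qpcr_preset(), n_replicates = 3, seed = 1, noise_sd = 0)
#' fold_change(ct, "Pitx2c", "Gapdh", "CON_LA", "CON_RA")$fold   # 160
generate_ct_table <- function(preset = qpcr_preset(), n_replicates = 6L, seed = 1L,
                              noise_sd = NULL) {
  if (!inherits(preset, "qpcr_preset")) config_error("preset must be a qpcr_preset")
  if (!is_count(n_replicates) || n_replicates < 2) config_error("n_replicates must be >= 2")
  noise_sd <- noise_sd %||% preset$noise_sd
  genes <- c(preset$genes, preset$reference_gene)
  grid <- expand.grid(replicate = seq_len(n_replicates), gene = genes,
                      group = preset$groups, stringsAsFactors = FALSE)
  true_ct <- mapply(function(gene, group) {
    if (gene == preset$reference_gene) preset$reference_ct
    else preset$reference_ct + preset$delta_ct[gene, group]
  }, grid$gene, grid$group)
  ct <- if (noise_sd > 0) {
    true_ct + with_seed(seed, stats::rnorm(nrow(grid), 0, noise_sd))
  } else {
    true_ct
  }
  data.frame(
    sample_id = sprintf("%s_r%d", grid$group, grid$replicate),
    group = grid$group,
    gene = grid$gene,
    ct = as.numeric(ct),
    stringsAsFactors = FALSE
  )
}
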