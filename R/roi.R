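## Desikan-Killiany gyral labels (34 per hemisphere) plus six deep
## gray-matter structures per hemisphere, as produced by a standard
## whole-brain anatomical parcellation. Used for default ROI naming.
.dk_cortical <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal",
  "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
  "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
  "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
  "transversetemporal"
)

.dk_subcortical <- c(
  "accumbens", "amygdala", "caudate", "hippocampus", "pallidum", "putamen"
)

#' Anatomical ROI labels
#'
#' Returns the default region-of-interest label set: 34 cortical gyral
#' parcels and 6 subcortical structures, each in both hemispheres, for 80
#' regions in total. Labels are identifiers only; no geometry is attached.
#'
#' @param n_cortical number of cortical parcels per hemisphere.
#' @param n_subcortical number of subcortical structures per hemisphere.
#' @return character vector of `2 * (n_cortical + n_subcortical)` labels,
#'   prefixed `lh_` and `rh_`.
#' @examples
#' length(roi_labels()) # 80
#' @export
roi_labels <- function(n_cortical = 34, n_subcortical = 6) {
  stopifnot(
    n_cortical >= 0, n_cortical <= length(.dk_cortical),
    n_subcortical >= 0, n_subcortical <= length(.dk_subcortical)
  )
  base <- c(.dk_cortical[seq_len(n_cortical)],
            .dk_subcortical[seq_len(n_subcortical)])
  c(paste0("lh_", base), paste0("rh_", base))
}
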