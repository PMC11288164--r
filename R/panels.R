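#' Build a reference/outgroup panel table
#'
#' A panel pairs, for one NDE family, the curated reference proteins with the
#' outgroup proteins used as negative controls (experimentally characterised
#' non-NDE relatives: xanthine dehydrogenase large subunits for NdhB/NdhL,
#' group II intron reverse transcriptases for NicX/NicA1). A family may have
#' no outgroups (NicA2), in which case the outgroup-based filters are
#' bypassed for it.
#'
#' @param references Record tibble (see [read_fasta()]) of reference proteins;
#'   must be non-empty.
#' @param nde_type One of `"NdhB"`, `"NdhL"`, `"NicX"`, `"NicA1"`, `"NicA2"`.
#' @param outgroups Record tibble of outgroup proteins; may have zero rows.
#' @return A tibble of class `nde_panels` with columns `nde_type`, `role`
#'   (`"reference"` or `"outgroup"`), `id`, `sequence`.
#' @export
reference_panel <- function(references, nde_type, outgroups = NULL) {
  if (!nde_type %in% NDE_TYPES) {
    abort(sprintf(
      "nde_type must be one of %s", paste(NDE_TYPES, collapse = ", ")
    ))
  }
  references <- validate_records(references, require_source = FALSE)
  if (nrow(references) == 0) {
    abort(sprintf("panel '%s' has no reference sequences", nde_type))
  }
  if (is.null(outgroups)) {
    outgroups <- tibble(id = character(), sequence = character())
  } else {
    outgroups <- validate_records(outgroups, require_source = FALSE)
  }
  if (length(intersect(references$id, outgroups$id)) > 0) {
    abort(sprintf(
      "panel '%s': reference and outgroup ids overlap (%s)", nde_type,
      intersect(references$id, outgroups$id)[1]
    ))
  }
  out <- bind_rows(
    tibble(
      nde_type = nde_type, role = "reference",
      id = references$id, sequence = references$sequence
    ),
    tibble(
      nde_type = nde_type, role = "outgroup",
      id = outgroups$id, sequence = outgroups$sequence
    )
  )
  class(out) <- c("nde_panels", class(out))
  out
}

#' Load reference panels from a configuration file
#'
#' The configuration is a flat YAML mapping of NDE family name to the FASTA
#' paths of its reference and (optional) outgroup sequences:
#'
#' ```yaml
#' NicX:
#'   references: nicx_refs.faa
#'   outgroups: nicx_out.faa
#' NicA2:
#'   references: nica2_refs.faa
#' ```
#'
#' Relative paths are resolved against the configuration file's directory.
#'
#' @param config_path Path to the YAML panel configuration.
#' @return An `nde_panels` tibble covering every configured family.
#' @export
load_reference_panel <- function(config_path) {
  if (!file.exists(config_path)) {
    abort(sprintf("panel configuration not found: %s", config_path))
  }
  cfg <- yaml::read_yaml(config_path)
  if (!is.list(cfg) || length(cfg) == 0) {
    abort("panel configuration is empty")
  }
  base <- dirname(config_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  panels <- purrr::imap(cfg, function(entry, type) {
    if (is.null(entry$references)) {
      abort(sprintf("panel '%s' configures no reference FASTA", type))
    }
    refs <- read_fasta(resolve(entry$references), source_id = "panel")
    outs <- NULL
    if (!is.null(entry$outgroups)) {
      outs <- read_fasta(resolve(entry$outgroups), source_id = "panel")
    }
    reference_panel(refs, nde_type = type, outgroups = outs)
  })
  out <- bind_rows(panels)
  class(out) <- c("nde_panels", class(out))
  out
}

panel_for_type <- function(panels, type) {
  p <- dplyr::filter(as_tibble(panels), .data$nde_type == type)
  if (nrow(dplyr::filter(p, .data$role == "reference")) == 0) {
    abort(sprintf("no reference sequences for nde_type '%s'", type))
  }
  p
}

panel_refs <- function(panel) {
  dplyr::filter(as_tibble(panel), .data$role == "reference")
}

panel_outs <- function(panel) {
  dplyr::filter(as_tibble(panel), .data$role == "outgroup")
}
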