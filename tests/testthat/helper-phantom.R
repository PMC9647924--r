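# Phantom fixtures are generated in code and cached per test run; cases are
# keyed by their configuration so repeated requests are free.

.tc_cache <- new.env(parent = emptyenv())

tc_case <- function(seed = 7, ...) {
  key <- paste0("case_", seed, "_", paste(deparse(list(...)), collapse = ""))
  if (is.null(.tc_cache[[key]]))
    .tc_cache[[key]] <- generate_phantom_case(phantom_config(seed = seed, ...))
  .tc_cache[[key]]
}

# Repository built from three phantom panoramics with their gold labels.
tc_repo <- function(seeds = 101:103) {
  key <- paste0("repo_", paste(seeds, collapse = "_"))
  if (is.null(.tc_cache[[key]]))
    .tc_cache[[key]] <- build_repository(lapply(seeds, function(s) {
      cs <- tc_case(seed = s)
      list(image = cs$panoramic$image, annotations = cs$panoramic$teeth,
           source_id = paste0("pan", s))
    }))
  .tc_cache[[key]]
}

# Extract crops and gold labels from the periapicals of a case.
tc_periapical_crops <- function(case) {
  out <- list()
  for (pa in case$periapicals) {
    cej <- connect_cej(pa$cej_mask)
    bx <- boxes_from_intraoral(pa$tooth_mask, cej, pa$position)
    crops <- crop_teeth(pa$image, bx, pa$id)
    for (i in seq_along(crops))
      out[[length(out) + 1L]] <- list(crop = crops[[i]],
                                      true_fdi = pa$teeth$fdi[i])
  }
  out
}
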