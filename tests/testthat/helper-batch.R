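# The standard 20-morphology batch is expensive to mesh, and several
# acceptance properties are measured on the same grown meshes; build it
# once, lazily, and share it across test blocks.
.batch_cache <- new.env(parent = emptyenv())

grown_batch <- function() {
  if (is.null(.batch_cache$grown)) {
    .batch_cache$grown <- lapply(morphology_batch(), grow_neuron)
  }
  .batch_cache$grown
}
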