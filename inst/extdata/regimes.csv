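species_id,regime,substrategy
Amobia_signata,SAT,satellite
Apodacra_seriemaculata,SAT,satellite
Craticulina_tabaniformis,SAT,satellite
Eumacronychia_persolla,NON_SAT,
Metopia_argyrocephala,NON_SAT,hole_searcher
Miltogramma_germari,SAT,satellite
Miltogramma_punctata,SAT,satellite
Miltogramma_turanica,SAT,satellite
Phrosinella_fedtshenkoi,NON_SAT,
Phrosinella_kocaki,NON_SAT,
Phylloteles_pictipennis,NON_SAT,necrophagous
Pterella_melanura,SAT,satellite
Senotainia_albifrons,SAT,satellite
Senotainia_conica,SAT,satellite
Senotainia_tricuspis,SAT,satellite
Sphenometopa_claripennis,NON_SAT,
Taxigramma_heteroneura,NON_SAT,stalker_lurker
Taxigramma_stictica,NON_SAT,stalker_lurker
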