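species_id,trait,mean,se
Amobia_signata,F_length,285.7,17.8
Amobia_signata,P_length,232.4,8.0
Amobia_signata,A_length,540.7,46.1
Amobia_signata,ANT_length,1058.8,60.5
Apodacra_seriemaculata,F_length,464.9,34.7
Apodacra_seriemaculata,P_length,173.0,6.0
Apodacra_seriemaculata,A_length,180.1,27.7
Apodacra_seriemaculata,ANT_length,818.0,54.6
Craticulina_tabaniformis,F_length,498.9,24.5
Craticulina_tabaniformis,P_length,240.6,5.0
Craticulina_tabaniformis,A_length,358.6,23.0
Craticulina_tabaniformis,ANT_length,1241.3,42.2
Eumacronychia_persolla,F_length,418.8,70.5
Eumacronychia_persolla,P_length,255.3,8.7
Eumacronychia_persolla,A_length,1005.8,59.7
Eumacronychia_persolla,ANT_length,1679.7,128.5
Metopia_argyrocephala,F_length,625.4,45.6
Metopia_argyrocephala,P_length,204.7,6.5
Metopia_argyrocephala,A_length,761.8,25.4
Metopia_argyrocephala,ANT_length,1571.5,68.3
Miltogramma_germari,F_length,339.3,28.2
Miltogramma_germari,P_length,232.3,4.2
Miltogramma_germari,A_length,449.7,29.6
Miltogramma_germari,ANT_length,1021.3,44.3
Miltogramma_punctata,F_length,326.9,23.6
Miltogramma_punctata,P_length,221.9,5.0
Miltogramma_punctata,A_length,404.4,10.2
Miltogramma_punctata,ANT_length,953.1,33.2
Miltogramma_turanica,F_length,330.9,13.6
Miltogramma_turanica,P_length,211.9,7.3
Miltogramma_turanica,A_length,363.4,11.2
Miltogramma_turanica,ANT_length,901.8,20.1
Phrosinella_fedtshenkoi,F_length,470.1,31.9
Phrosinella_fedtshenkoi,P_length,189.4,4.2
Phrosinella_fedtshenkoi,A_length,544.3,30.4
Phrosinella_fedtshenkoi,ANT_length,1203.8,52.7
Phrosinella_kocaki,F_length,471.3,22.8
Phrosinella_kocaki,P_length,193.6,6.7
Phrosinella_kocaki,A_length,487.1,29.9
Phrosinella_kocaki,ANT_length,1152.0,42.0
Phylloteles_pictipennis,F_length,378.6,7.9
Phylloteles_pictipennis,P_length,188.6,4.2
Phylloteles_pictipennis,A_length,571.4,28.0
Phylloteles_pictipennis,ANT_length,1146.4,27.1
Pterella_melanura,F_length,271.3,22.2
Pterella_melanura,P_length,180.7,7.0
Pterella_melanura,A_length,285.9,22.9
Pterella_melanura,ANT_length,737.8,27.4
Senotainia_albifrons,F_length,262.7,20.6
Senotainia_albifrons,P_length,191.7,5.8
Senotainia_albifrons,A_length,411.5,34.8
Senotainia_albifrons,ANT_length,865.8,37.7
Senotainia_conica,F_length,199.3,22.2
Senotainia_conica,P_length,177.1,7.0
Senotainia_conica,A_length,395.3,17.5
Senotainia_conica,ANT_length,771.7,40.8
Senotainia_tricuspis,F_length,335.5,24.2
Senotainia_tricuspis,P_length,222.0,2.7
Senotainia_tricuspis,A_length,576.0,31.5
Senotainia_tricuspis,ANT_length,1133.5,15.3
Sphenometopa_claripennis,F_length,423.9,25.9
Sphenometopa_claripennis,P_length,190.9,4.8
Sphenometopa_claripennis,A_length,521.3,16.7
Sphenometopa_claripennis,ANT_length,1127.7,21.7
Taxigramma_heteroneura,F_length,242.0,15.5
Taxigramma_heteroneura,P_length,175.5,6.8
Taxigramma_heteroneura,A_length,452.3,31.0
Taxigramma_heteroneura,ANT_length,870.2,46.0
Taxigramma_stictica,F_length,284.3,7.2
Taxigramma_stictica,P_length,187.6,4.3
Taxigramma_stictica,A_length,542.3,31.8
Taxigramma_stictica,ANT_length,1017.8,31.7
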