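species,common_name,status_global,status_national,status_regional_1,status_regional_2
Carcharhinus brachyurus,copper shark,NT,DD,-,-
Carcharhinus falciformis,silky shark,NT,NT,-,-
Galeorhinus galeus,school shark,VU,CR,CR,-
Gymnura altavela,butterfly ray,VU,CR,EN,-
Myliobatis goodei,southern eagle ray,DD,CR,CR,-
Narcine brasiliensis,Brazilian electric ray,DD,DD,-,-
Prionace glauca,blue shark,NT,NT,VU,-
Pseudobatos horkelii,Brazilian guitarfish,CR,CR,CR,CR
Rhizoprionodon lalandii,Brazilian sharpnose shark,DD,NT,-,-
Rhizoprionodon porosus,Caribbean sharpnose shark,LC,DD,-,-
Sphyrna lewini,scalloped hammerhead shark,EN,CR,CR,EN
Sphyrna zygaena,smooth hammerhead,VU,CR,CR,EN
Squalus cubensis,Cuban dogfish,DD,-,-,-
Squalus mitsukurii,shortspine spurdog,DD,DD,-,-
Squatina guggenheim,spiny angel shark,EN,CR,CR,EN
Squatina occulta,smoothback angel shark,EN,CR,CR,-
Zapteryx brevirostris,shortnose guitarfish,VU,VU,CR,-
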