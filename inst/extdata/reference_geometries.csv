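"object_class","quantity","mean_nm","sd_nm","n","source"
"helical_tube","tube_diameter",23.9,3.7,NA,"cryo-EM, membrane tube diameter"
"helical_tube","outer_diameter",82.3,6.1,NA,"cryo-EM, superhelix outer diameter"
"helical_tube","axial_pitch",53.1,7.6,NA,"cryo-EM, superhelix pitch"
"zigzag_ribbon","ribbon_diameter",46.2,4.9,NA,"cryo-EM, zigzag tube-less ribbon"
"zigzag_ribbon","axial_pitch",39.8,6.9,NA,"cryo-EM, zigzag tube-less ribbon"
"sinusoidal_ribbon","ribbon_diameter",34.1,5,NA,"cryo-EM, sinusoidal tube-less ribbon"
"sinusoidal_ribbon","axial_pitch",55.7,8.5,NA,"cryo-EM, sinusoidal tube-less ribbon"
"sinusoidal_ribbon","ribbon_width",13.6,2.1,NA,"cryo-EM, sinusoidal tube-less ribbon"
"filament","thickness",4.9,0.5,NA,"negative stain, double-stranded filament"
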