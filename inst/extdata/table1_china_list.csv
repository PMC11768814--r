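name,level
Methamidophos,banned
Parathion,banned
Methyl parathion,banned
Monocrotophos,banned
Phosphoric acid,banned
Fenamiphos,banned
Fonofos,banned
Phosfolan-methyl,banned
Cadusafos,banned
Coumaphos,banned
Sulfotep,banned
Terbufos,banned
Methidathion,banned
Phorate,banned
Isofenphos-methyl,banned
Isocarbophos,banned
Ethoprophos,banned
Omethoate,restricted
Systox,restricted
Posfolan-methyl,restricted
Isazophos,restricted
Acephate,restricted
Dimethoate,restricted
Chlorpyrifos,restricted
Triazophos,restricted
Fenthion,unrestricted
Profenofos,unrestricted
Dichlorvos,unrestricted
Fosthiazate,unrestricted
Phenthoate,unrestricted
Dipterex,unrestricted
Phoxim,unrestricted
Quinalphos,unrestricted
Fenitrothion,unrestricted
Malathion,unrestricted
Propetamphos,unrestricted
Dicrotophos,unrestricted
Azinphos-methyl,unrestricted
EPN,unrestricted
Pyrazophos,unrestricted
Pyraclofos,unrestricted
Propaphos,unrestricted
Prothiofos,unrestricted
Dichlofenthion,unrestricted
Pyridiphenthion,unrestricted
Fosthietan,unrestricted
Tebupirimfos,unrestricted
Chlorfenvinphos,unrestricted
Diazinon,unrestricted
Isoxathion,unrestricted
Azinphos-ethyl,unrestricted
Dibrom,unrestricted
Famphur,unrestricted
Phosalone,unrestricted
Heptenophos,unrestricted
Acethion,unrestricted
Azamethiphos,unrestricted
Chlorpyrifos-methyl,unrestricted
Pirimiphos-methyl,unrestricted
Thiometon,unrestricted
Phosphocarb,unrestricted
Sulprofos,unrestricted
Chlormephos,unrestricted
Chlorethoxyfos,unrestricted
Isophenphos,unrestricted
Mecarbam,unrestricted
Naftalofos,unrestricted
Tetrachlorvinphos,unrestricted
Cyanophos,unrestricted
Temephos,unrestricted
Mevinphos,unrestricted
Fensulfothion,unrestricted
Mecarbam,unrestricted
Phosemet,unrestricted
Oxydemeton-methyl,unrestricted
Disulfoton,unrestricted
Ethion,unrestricted
Thionazin,unrestricted
Kitazine,unrestricted
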