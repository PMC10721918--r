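province,region
Beijing,East
Tianjin,East
Hebei,East
Liaoning,East
Shanghai,East
Jiangsu,East
Zhejiang,East
Fujian,East
Shandong,East
Guangdong,East
Hainan,East
Shanxi,Central&West
Jilin,Central&West
Heilongjiang,Central&West
Anhui,Central&West
Jiangxi,Central&West
Henan,Central&West
Hubei,Central&West
Hunan,Central&West
Guangxi,Central&West
Chongqing,Central&West
Sichuan,Central&West
Guizhou,Central&West
Yunnan,Central&West
Shaanxi,Central&West
Gansu,Central&West
Ningxia,Central&West
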