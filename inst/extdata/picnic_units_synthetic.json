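{"units":{"picnic":"picnic","fisherman":["fisherman","angler"],"clouds":"cloud","basket":["basket","hamper"],"girl":["girl","daughter"],"boy":["boy","son"],"man":["man","father","dad"],"woman":["woman","mother","mom"],"dog":["dog","puppy"],"kite":"kite","flag":"flag","sailboat":["sailboat","boat"],"lake":["lake","pond"],"tree":"tree","house":["house","cottage"],"blanket":"blanket","radio":"radio","book":"book","shoe":["shoe","sneaker"],"pier":["pier","dock"],"pole":["pole","fishing pole","rod"],"water":"water","sand":["sand","beach"],"shore":["shore","shoreline"],"car":["car","automobile"],"bird":"bird","ball":"ball","cup":["cup","mug"],"plate":"plate","sandwich":"sandwich","hat":["hat","cap"],"grass":["grass","lawn"]},"theme_unit":"picnic"}
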